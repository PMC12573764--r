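# Shared small systems and utilities, built once per test run.

.sys_cache <- new.env()

.cached <- function(key, builder) {
  if (!exists(key, envir = .sys_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .sys_cache)
  }
  get(key, envir = .sys_cache)
}

h2_mini <- function() .cached("h2_mini", function() {
  build_ao_integrals(generate_fixture("diatomic", symbols = c("H", "H"),
                                      R = 0.74), "mini")
})

h2_svb <- function() .cached("h2_svb", function() {
  build_ao_integrals(generate_fixture("diatomic", symbols = c("H", "H"),
                                      R = 0.74), "svb")
})

water_mini <- function() .cached("water_mini", function() {
  build_ao_integrals(generate_fixture("water"), "mini")
})

water_hf <- function() .cached("water_hf", function() {
  run_scf(water_mini(), "hf", scf_settings())
})

water_pbe0 <- function() .cached("water_pbe0", function() {
  run_scf(water_mini(), "pbe0", scf_settings())
})

h4_ints <- function() .cached("h4_ints", function() {
  build_ao_integrals(molecule(rep("H", 4), cbind(0, 0, c(0, 0.9, 1.8, 2.9))),
                     "mini")
})

# random determinant with S-orthonormal orbitals for a given system
random_det <- function(ints, n_alpha, n_beta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- ints$M
  X <- nocicoox:::.invsqrtm_sym(ints$S)
  occ <- function(n) {
    o <- numeric(M)
    o[seq_len(n)] <- 1
    o
  }
  list(Ca = X %*% qr.Q(qr(matrix(rnorm(M * M), M))),
       Cb = X %*% qr.Q(qr(matrix(rnorm(M * M), M))),
       occ_a = occ(n_alpha), occ_b = occ(n_beta),
       n_alpha = n_alpha, n_beta = n_beta)
}

# copy a determinant with modified occupation vectors
within_occ <- function(d, occ_a = NULL, occ_b = NULL) {
  if (!is.null(occ_a)) d$occ_a <- occ_a
  if (!is.null(occ_b)) d$occ_b <- occ_b
  d
}
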