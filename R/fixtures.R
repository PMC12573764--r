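# Deterministic geometry generators for the test systems: diatomics,
# water, all-E polyene chains, bond-length-alternation butadiene, and
# twisted/pyramidalized ethylene.  Idealized standard bond lengths and
# angles; all coordinates in Angstrom.

.rot_inplane <- function(v, angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], 0)
}

.fixture_polyene <- function(n, d_double = 0, d_single = 0) {
  if (n < 1 || n != round(n)) stop("polyene index n must be a positive integer")
  nc <- 2L * as.integer(n)
  L_db <- 1.34 + d_double
  L_sg <- 1.46 + d_single
  if (L_db <= 0.5 || L_sg <= 0.5) stop("unphysical bond displacement")
  delta <- 28  # half the deviation of the CCC angle (124 deg) from linear
  cpos <- matrix(0, nc, 3)
  dirs <- matrix(0, nc - 1, 3)
  for (k in seq_len(nc - 1)) {
    L <- if (k %% 2 == 1) L_db else L_sg
    sgn <- if (k %% 2 == 1) 1 else -1
    d <- c(cos(delta * pi / 180), sgn * sin(delta * pi / 180), 0)
    dirs[k, ] <- d
    cpos[k + 1, ] <- cpos[k, ] + L * d
  }
  ch <- 1.09
  hpos <- list()
  # terminal CH2 groups: two in-plane H at +-121 deg from the backbone bond
  for (h in c(121, -121)) {
    hpos[[length(hpos) + 1]] <- cpos[1, ] + ch * .rot_inplane(-dirs[1, ], h)
  }
  # inner CH: H opposite the bond-angle bisector
  if (nc > 2) {
    for (i in 2:(nc - 1)) {
      b <- -(dirs[i - 1, ] - dirs[i, ])  # in-plane normal-ish direction
      b <- -(normalize_vec(dirs[i - 1, ]) - normalize_vec(dirs[i, ]))
      bis <- normalize_vec(normalize_vec(-dirs[i - 1, ]) +
                             normalize_vec(dirs[i, ]))
      hpos[[length(hpos) + 1]] <- cpos[i, ] - ch * bis
    }
  }
  for (h in c(121, -121)) {
    hpos[[length(hpos) + 1]] <- cpos[nc, ] + ch * .rot_inplane(dirs[nc - 1, ], h)
  }
  coords <- rbind(cpos, do.call(rbind, hpos))
  molecule(c(rep("C", nc), rep("H", nrow(coords) - nc)), coords)
}

normalize_vec <- function(v) v / sqrt(sum(v^2))

.fixture_water <- function() {
  r <- 0.9572
  a <- 104.52 * pi / 180
  molecule(
    c("O", "H", "H"),
    rbind(c(0, 0, 0),
          c(r, 0, 0),
          c(r * cos(a), r * sin(a), 0))
  )
}

.fixture_diatomic <- function(symbols, R, charge = 0, multiplicity = NULL) {
  if (length(symbols) != 2) stop("diatomic needs exactly two element symbols")
  if (R <= 0.2 || R > 200) stop("unphysical bond length ", R, " Angstrom")
  molecule(symbols, rbind(c(0, 0, 0), c(0, 0, R)),
           charge = charge, multiplicity = multiplicity)
}

.fixture_pyramidalized_ethylene <- function(theta_deg) {
  if (abs(theta_deg) > 130) stop("pyramidalization angle out of range")
  rcc <- 1.40  # stretched C=C of the twisted diradical geometry
  rch <- 1.08
  hcc <- 121 * pi / 180
  th <- theta_deg * pi / 180
  # C1 CH2 in the xz-plane, pyramidalized by rotation about local x
  hx <- sin(hcc)
  hz <- -cos(hcc)
  h1a <- c(rch * hx, rch * hz * sin(th), rch * hz * cos(th))
  h1b <- c(-rch * hx, rch * hz * sin(th), rch * hz * cos(th))
  # C2 CH2 in the yz-plane (90 degree twist)
  h2a <- c(0, rch * hx, rcc - rch * hz)
  h2b <- c(0, -rch * hx, rcc - rch * hz)
  molecule(
    c("C", "C", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(0, 0, rcc), h1a, h1b, h2a, h2b)
  )
}

#' Generate a test geometry
#'
#' Families: `"water"`; `"diatomic"` (params: `symbols`, `R` in Angstrom,
#' optional `charge`, `multiplicity`); `"polyene"` (param `n`, giving the
#' all-E chain C2nH2n+2); `"bla-butadiene"` (param `disp` in Angstrom:
#' double bonds stretched and the single bond compressed by `disp`);
#' `"pyramidalized-ethylene"` (param `theta` in degrees, the
#' pyramidalization angle of one CH2 of 90-degree-twisted ethylene).
#'
#' @param family fixture family name
#' @param ... family parameters, see above
#' @return a `Molecule`
#' @export
generate_fixture <- function(family, ...) {
  args <- list(...)
  switch(family,
    water = .fixture_water(),
    diatomic = .fixture_diatomic(args$symbols, args$R,
                                 charge = args$charge %||% 0,
                                 multiplicity = args$multiplicity),
    polyene = .fixture_polyene(args$n),
    `bla-butadiene` = .fixture_polyene(2, d_double = args$disp %||% 0,
                                       d_single = -(args$disp %||% 0)),
    `pyramidalized-ethylene` = .fixture_pyramidalized_ethylene(args$theta %||% 0),
    stop("unknown fixture family: ", family)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
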