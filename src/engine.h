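#pragma once
#include <RcppArmadillo.h>
// shared between translation units
Rcpp::List ao_values_impl(const Rcpp::List& basis,
                          const Rcpp::NumericMatrix& pts, bool deriv);
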