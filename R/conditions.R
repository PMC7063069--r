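## Classified conditions so the command-line layer can map failures to exit
## codes (bad input -> 2, geometry -> 3) without string matching.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ifp_input_error", "ifp_error")))
}

stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("ifp_geometry_error", "ifp_error")))
}

is_num <- function(x, n = NULL) {
  is.numeric(x) && all(is.finite(x)) && (is.null(n) || length(x) == n)
}
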