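# Classed conditions so callers (and the CLI wrapper) can distinguish
# bad configuration / bad input files from internal invariant violations.

config_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tecontrib_config_error", "tecontrib_error")))
}

parse_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tecontrib_parse_error", "tecontrib_error")))
}

input_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tecontrib_input_error", "tecontrib_error")))
}

invariant_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tecontrib_invariant_error", "tecontrib_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

# largest-remainder apportionment of n items over fractions summing to 1;
# returns integer counts summing exactly to n
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
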