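`%||%` <- function(a, b) if (is.null(a)) b else a

nc_log <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Write a table as TSV with stable column order
#'
#' All pipeline outputs go through this helper so that reruns with the same
#' inputs are byte-identical.
#'
#' @param x data frame
#' @param path output path
#' @export
write_tsv_stable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_stable
#' @export
read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

# Deterministic per-stage child seed from one global seed.  Keeps results
# of a stage invariant to whether earlier stages ran in the same session.
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, summarize = 23L, pca = 37L, screen = 41L,
            consistency = 53L, patchseq = 67L)
  o <- offs[[stage]] %||% 97L
  as.integer((as.numeric(seed) * 1009 + o) %% 2147483647)
}
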