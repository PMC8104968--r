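#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils read.table write.table head modifyList packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

#' Derive a child seed from a global seed
#'
#' Deterministically spawns per-stage seeds from one global seed so that
#' pipeline stages are individually reproducible without seed collisions.
#' Results stay below 2^31 so they are valid R integer seeds.
#'
#' @param seed integer global seed.
#' @param index stage index (1-based) or any small integer tag.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, index) {
  seed <- check_count(seed, "seed", min = 0L)
  index <- check_count(index, "index", min = 0L)
  as.integer((as.double(seed) * 48271 + index * 1009 + 17) %% 2147483629)
}

# Write a data.frame as TSV (no quoting, no row names) -- the package's
# uniform tabular output format.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

# Write a numeric matrix as TSV with an id column for row names.
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m) %||% as.character(seq_len(nrow(m))),
                   as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
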