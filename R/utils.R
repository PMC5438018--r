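#' @keywords internal
"_PACKAGE"

#' @importFrom stats dbinom dhyper median p.adjust rbinom rnorm runif setNames
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## typed conditions: every hard error carries class "hemiassoc_error" plus a
## specific subclass so callers (and tests) can dispatch on the failure kind
stop_hemiassoc <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "hemiassoc_error"),
                      call = call))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == round(x)
}

## deterministic sub-seed for a named stage, so independent output files get
## independent but reproducible RNG streams from one master seed
derive_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483647)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

#' Read a sample manifest
#'
#' The manifest is a tab-separated file with header columns `sample_id`,
#' `group` (`case` or `control`) and `age` (years).
#'
#' @param path Path to the manifest TSV.
#' @return A data frame with columns `sample_id`, `group`, `age`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_hemiassoc(sprintf("manifest not found: %s", path),
                   "hemiassoc_missing_file")
  }
  m <- read_tsv(path, colClasses = c("character", "character", "numeric"))
  required <- c("sample_id", "group", "age")
  if (!all(required %in% names(m))) {
    stop_hemiassoc("manifest must have columns sample_id, group, age",
                   "hemiassoc_bad_manifest")
  }
  if (!all(m$group %in% c("case", "control"))) {
    stop_hemiassoc("manifest group labels must be 'case' or 'control'",
                   "hemiassoc_bad_manifest")
  }
  if (anyDuplicated(m$sample_id)) {
    stop_hemiassoc("duplicated sample ids in manifest",
                   "hemiassoc_bad_manifest")
  }
  m[required]
}
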