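# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All generator randomness flows through this; no hidden state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Convert a coefficient of variation on the natural scale to the standard
# deviation of the matching log2-normal noise term.
cvToLog2Sd <- function(cv) {
  stopifnot(cv >= 0)
  sqrt(log(1 + cv^2)) / log(2)
}

#' @importFrom stats median
ncCenter <- function(values, center = c("median", "mean")) {
  center <- match.arg(center)
  if (all(is.na(values))) return(NA_real_)
  if (center == "median") median(values, na.rm = TRUE) else mean(values, na.rm = TRUE)
}

.readDelim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""),
                    quote = "\"", comment.char = "")
}

.writeDelim <- function(df, path) {
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

PERTURBATION_RESERVED <- c("NC", "PLK1", "EMPTY")
ARMS <- c("VEHICLE", "CISPLATIN")
GENDERS <- c("FEMALE", "MALE")
STAGES <- c("I", "II", "III", "IV")
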