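# Small shared helpers: sequence utilities, rounding, table IO.

#' Reverse complement of an ACGT string
#'
#' Strict uppercase ACGT alphabet; any other character is an error.
#'
#' @param x a single character string.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  check_acgt(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

check_acgt <- function(x) {
  if (grepl("[^ACGT]", x)) stop("invalid alphabet: sequence must be uppercase ACGT only")
  invisible(TRUE)
}

#' Round half away from zero to a fixed number of decimals
#'
#' Report percentages are rounded half-up to one decimal (so 65.55 prints as
#' 65.6), unlike base \code{round()} which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Plain TSV readers/writers: single header line, tab separated, never quoted.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# Run a block under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# random ACGT string of length n (uses the current RNG stream)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
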