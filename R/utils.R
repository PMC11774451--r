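## Small internal helpers shared across modules.

#' @importFrom withr with_seed
#' @importFrom stats rnorm runif sd cor
NULL

## Derive a reproducible sub-seed from a base seed and a stable component tag.
## Keeps results < 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

## Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

clamp_scalar <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

## All-pairs Euclidean distances between the rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Random proper rotation (Haar via QR sign fix).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Write a text file atomically: write to a temp file in the same directory,
## then rename. Partial runs never leave truncated outputs.
atomic_write_lines <- function(lines, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

atomic_write_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

## Three-letter -> one-letter amino-acid code map for the 20 standard residues.
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1 <- unname(AA3TO1)
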