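#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate codes used in consensus strings. Lowercase two-base codes
# follow the three-tier consensus notation (uppercase base / lowercase pair /
# '.'); uppercase multi-base codes are accepted on input for database files.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  r = c("A", "G"), y = c("C", "T"), s = c("C", "G"),
  w = c("A", "T"), k = c("G", "T"), m = c("A", "C"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  b = c("C", "G", "T"), d = c("A", "G", "T"),
  h = c("A", "C", "T"), v = c("A", "C", "G"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  n = DNA_BASES, N = DNA_BASES, "." = DNA_BASES
)

IUPAC_FROM <- "ACGTUacgtuRYSWKMryswkmBDHVbdhvNn."
IUPAC_TO   <- "TGCAAtgcaaYRSWMKyrswmkVHDBvhdbNn."

#' Reverse complement of DNA / IUPAC strings
#'
#' Vectorised over `x`. Handles plain `ACGTN` words as well as IUPAC
#' degenerate consensus strings (both cases; `.` maps to itself).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr(IUPAC_FROM, IUPAC_TO, x)
  w <- nchar(comp)
  if (length(x) == 0L) return(character(0))
  if (length(unique(w)) == 1L) {
    wd <- w[1]
    if (wd == 0L) return(comp)
    if (wd > 64L || length(comp) <= 4L) {
      # few/long strings: per-string character reversal
      vapply(comp, function(s) {
        paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
    } else {
      # many short equal-width words: column-wise reversal
      do.call(paste0, lapply(wd:1, function(i) substring(comp, i, i)))
    }
  } else {
    # mixed widths: recurse on equal-width groups
    out <- character(length(comp))
    for (g in split(seq_along(comp), w)) out[g] <- revcomp(x[g])
    out
  }
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a stream of child seeds from one parent seed, keeping them within
# the 32-bit integer range R requires.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sliding windows of width w over one string; character(0) when too short.
str_windows <- function(s, w) {
  L <- nchar(s)
  if (L < w) return(character(0))
  substring(s, seq_len(L - w + 1L), w:L)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
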