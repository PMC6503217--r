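# Low-level sequence utilities shared by the simulator and the alignment
# engines. DNA travels as character strings at the API surface and as integer
# vectors (0=A, 1=C, 2=G, 3=T, 4=other) internally.

DNA_BASES <- c("A", "C", "G", "T")

.dna_lookup <- local({
  lut <- rep(4L, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("t") + 1L] <- 3L
  lut
})

#' Encode a DNA string as an integer vector (A=0, C=1, G=2, T=3, other=4)
#' @param x single DNA string
#' @return integer vector
#' @keywords internal
encode_dna <- function(x) {
  .dna_lookup[utf8ToInt(x) + 1L]
}

#' Decode an integer vector back to a DNA string
#' @param v integer vector as produced by [encode_dna()]
#' @return single string
#' @keywords internal
decode_dna <- function(v) {
  intToUtf8(c(65L, 67L, 71L, 84L, 78L)[pmin(v, 4L) + 1L])
}

#' Reverse complement of an encoded DNA vector
#' @param v integer vector
#' @return integer vector
#' @keywords internal
revcomp_int <- function(v) {
  out <- rev(v)
  ok <- out < 4L
  out[ok] <- 3L - out[ok]
  out
}

#' Reverse complement of a DNA string
#' @param x DNA string
#' @return DNA string
#' @export
revcomp <- function(x) {
  decode_dna(revcomp_int(encode_dna(x)))
}

.genetic_code <- function() {
  if (is.null(.rc$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .rc$gc <- setNames(as.character(gc), names(gc))
  }
  .rc$gc
}

#' Translate a coding sequence under the standard genetic code
#'
#' Length must be divisible by 3. A trailing stop codon is dropped; internal
#' stops are rendered as `*` (callers decide whether that is an error).
#' @param cds DNA string
#' @return protein string
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(toupper(cds), seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# the 61 sense codons as a 61 x 3 integer matrix (encoded bases)
.sense_codons <- function() {
  if (is.null(.rc$sense)) {
    gc <- .genetic_code()
    sense <- names(gc)[gc != "*"]
    m <- t(vapply(sense, function(cd) encode_dna(cd), integer(3)))
    rownames(m) <- sense
    .rc$sense <- m
  }
  .rc$sense
}

.stop_codons <- c("TAA", "TAG", "TGA")

.is_stop_codon <- function(b1, b2, b3) {
  # TAA = 3,0,0 ; TAG = 3,0,2 ; TGA = 3,2,0
  (b1 == 3L) & ((b2 == 0L & (b3 == 0L | b3 == 2L)) | (b2 == 2L & b3 == 0L))
}

#' Random stop-free coding sequence (encoded)
#' @param n_codons number of codons
#' @return integer vector of length 3 * n_codons
#' @keywords internal
random_cds_int <- function(n_codons) {
  sense <- .sense_codons()
  idx <- sample.int(nrow(sense), n_codons, replace = TRUE)
  as.integer(t(sense[idx, , drop = FALSE]))
}

#' Random DNA (encoded)
#' @param n length
#' @return integer vector
#' @keywords internal
random_dna_int <- function(n) {
  sample(0:3, n, replace = TRUE)
}

#' Mutate an encoded sequence under JC69 for a branch of given length
#'
#' Each site changes with probability 3/4 (1 - exp(-4 d / 3)) and, when it
#' changes, takes one of the three other bases uniformly. When `coding` is
#' TRUE, mutations that would create an internal stop codon (frame starting at
#' position 1) are reverted, a biologically motivated guard that keeps
#' simulated genes translatable; the rejected fraction is < 1% of mutations.
#' @param v encoded sequence
#' @param d expected substitutions per site on the branch
#' @param coding revert stop-creating mutations
#' @return mutated encoded sequence
#' @keywords internal
mutate_jc69 <- function(v, d, coding = FALSE) {
  if (d <= 0 || length(v) == 0L) return(v)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- which(runif(length(v)) < p)
  if (length(hit) == 0L) return(v)
  old <- v[hit]
  shift <- sample.int(3L, length(hit), replace = TRUE)
  v[hit] <- (old + shift) %% 4L
  if (coding) {
    cod <- (hit - 1L) %/% 3L          # 0-based codon index of each hit
    check <- unique(cod)
    i1 <- check * 3L + 1L
    bad <- check[.is_stop_codon(v[i1], v[i1 + 1L], v[i1 + 2L]) &
                 i1 + 2L <= length(v)]
    if (length(bad) > 0L) {
      revert <- hit[cod %in% bad]
      v[revert] <- old[cod %in% bad]
    }
  }
  v
}

# amino-acid encoding for the C alignment kernel: LETTERS index 0..25
.encode_protein <- function(x) {
  v <- utf8ToInt(toupper(x)) - 65L
  if (any(v < 0L | v > 25L)) stop("illegal character in protein sequence")
  v
}

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

# 26 x 26 integer substitution matrix from Biostrings' BLOSUM62
.blosum62_26 <- function() {
  if (is.null(.rc$blosum)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    b <- env$BLOSUM62
    m <- matrix(-4L, 26L, 26L)
    letters_b <- rownames(b)[rownames(b) %in% LETTERS]
    for (x in letters_b) {
      for (y in letters_b) {
        m[utf8ToInt(x) - 64L, utf8ToInt(y) - 64L] <- as.integer(b[x, y])
      }
    }
    .rc$blosum <- m
  }
  .rc$blosum
}

# run expr with a reproducible, isolated RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
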