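# Internal residue alphabet and encoding.
#
# Residues are single uppercase characters:
#   bases        A C G T
#   ambiguity    R Y S W K M B D H V   (IUPAC)
#   missing      N                      ('?' is normalised to 'N' on input)
#   gap          -
#
# Integer encoding used by all numeric kernels:
#   0 = wildcard (missing or ambiguity -- both behave as "no information"),
#   1 = A, 2 = C, 3 = G, 4 = T, 5 = gap.
# Purines (A, G) are odd, pyrimidines (C, T) even, so a mismatch between
# defined bases is a transition iff the two codes have equal parity.

.BG_BASES <- c("A", "C", "G", "T")
.BG_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.BG_ALLOWED <- c(.BG_BASES, .BG_AMBIG, "N", "-")

.bg_code_table <- local({
  tab <- rep(0L, 256L)
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab[utf8ToInt("-") + 1L] <- 5L
  tab
})

#' @keywords internal
#' @noRd
encode_residues <- function(x) {
  .bg_code_table[utf8ToInt(paste(x, collapse = "")) + 1L]
}

# Encode a character alignment matrix (rows = accessions) into the integer
# alphabet. Row names are preserved.
#' @keywords internal
#' @noRd
encode_alignment <- function(mat) {
  enc <- matrix(encode_residues(t(mat)), nrow = nrow(mat), byrow = TRUE)
  rownames(enc) <- rownames(mat)
  enc
}

# Normalise raw residue characters: uppercase, '?' -> 'N'; error on anything
# outside the allowed alphabet, naming the offending symbol.
#' @keywords internal
#' @noRd
normalize_residues <- function(x, context = "sequence") {
  x <- toupper(x)
  x[x == "?"] <- "N"
  bad <- setdiff(unique(x), .BG_ALLOWED)
  if (length(bad) > 0L) {
    stop(sprintf("non-IUPAC character '%s' in %s", bad[[1L]], context),
         call. = FALSE)
  }
  x
}
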