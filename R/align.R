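# Alignment primitives: affine-gap global/local alignment over BLOSUM62
# and profile-profile alignment for the progressive MSA. The dynamic
# programming kernel lives in src/align.cpp; a gap of length k costs
# gap_open + k * gap_ext, traceback ties resolve diagonal > up > left.

.pk_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 matrix (from Biostrings), restricted to the
#' residue alphabet used here (20 amino acids plus X).
#'
#' @return Numeric matrix with dimnames over the residue alphabet.
#' @export
blosum62 <- function() {
  if (is.null(.pk_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- c(AA_ALPHABET, "X")
    .pk_env$blosum62 <- e$BLOSUM62[ab, ab]
  }
  .pk_env$blosum62
}

.sim_matrix <- function(a_chars, b_chars, sub_matrix) {
  ai <- match(a_chars, rownames(sub_matrix))
  bi <- match(b_chars, colnames(sub_matrix))
  if (anyNA(ai) || anyNA(bi)) stop("alignment: residue outside alphabet")
  sub_matrix[ai, bi, drop = FALSE]
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch alignment under a substitution matrix with affine gap
#' penalties. The traceback is deterministic (ties: diagonal, then gap in
#' the second sequence, then gap in the first).
#'
#' @param a,b Amino-acid strings or [protein_record] objects.
#' @param sub_matrix Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_ext Gap opening / extension penalties (a gap of
#'   length k costs `gap_open + k * gap_ext`).
#' @return List with `score`, `aligned_a`, `aligned_b` (gapped strings of
#'   equal length) and `identity` (fraction of aligned residue pairs that
#'   are identical).
#' @export
pairwise_align <- function(a, b, sub_matrix = blosum62(),
                           gap_open = 10, gap_ext = 1) {
  a <- if (inherits(a, "protein_record")) a$sequence else toupper(a)
  b <- if (inherits(b, "protein_record")) b$sequence else toupper(b)
  stopifnot(nzchar(a), nzchar(b))
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  res <- .align_dp(.sim_matrix(ac, bc, sub_matrix), gap_open, gap_ext, FALSE)
  ga <- ifelse(res$a_idx > 0, ac[pmax(res$a_idx, 1L)], "-")
  gb <- ifelse(res$b_idx > 0, bc[pmax(res$b_idx, 1L)], "-")
  both <- res$a_idx > 0 & res$b_idx > 0
  list(score = res$score,
       aligned_a = paste(ga, collapse = ""),
       aligned_b = paste(gb, collapse = ""),
       identity = if (any(both)) mean(ga[both] == gb[both]) else 0,
       a_idx = res$a_idx, b_idx = res$b_idx)
}

#' Local pairwise alignment with affine gaps
#'
#' Smith-Waterman alignment; used to anchor domain windows by aligning a
#' domain exemplar against a multi-domain protein.
#'
#' @inheritParams pairwise_align
#' @param mask Optional integer vector of 1-based positions in `b` whose
#'   similarity is suppressed (already-claimed regions).
#' @return List with `score`, `a_range` and `b_range` (1-based inclusive
#'   ranges of the aligned segments; `c(0, 0)` when there is no positive-
#'   scoring alignment).
#' @export
local_align <- function(a, b, sub_matrix = blosum62(),
                        gap_open = 10, gap_ext = 1, mask = NULL) {
  a <- if (inherits(a, "protein_record")) a$sequence else toupper(a)
  b <- if (inherits(b, "protein_record")) b$sequence else toupper(b)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  sim <- .sim_matrix(ac, bc, sub_matrix)
  if (length(mask)) sim[, mask] <- -1e6
  res <- .align_dp(sim, gap_open, gap_ext, TRUE)
  list(score = res$score, a_range = res$a_range, b_range = res$b_range)
}

# self-score of a sequence under the substitution matrix (perfect match)
.self_score <- function(seq, sub_matrix = blosum62()) {
  ch <- strsplit(seq, "")[[1]]
  sum(sub_matrix[cbind(match(ch, rownames(sub_matrix)),
                       match(ch, colnames(sub_matrix)))])
}

# ---- profiles (for progressive MSA) ------------------------------------

# a profile is a (21 x L) column-frequency matrix over AA_ALPHABET + gap
.profile_alphabet <- function() c(AA_ALPHABET, "X", "-")

.seqs_to_profile <- function(char_mat) {
  ab <- .profile_alphabet()
  apply(char_mat, 2, function(col) {
    tab <- tabulate(match(col, ab), nbins = length(ab))
    tab / length(col)
  })
}

# cross-score between profile columns; gaps score 0 against everything
.profile_sim <- function(pa, pb, sub_matrix) {
  ab <- .profile_alphabet()
  S <- matrix(0, length(ab), length(ab), dimnames = list(ab, ab))
  res <- setdiff(ab, "-")
  S[res, res] <- sub_matrix[res, res]
  t(pa) %*% S %*% pb
}

# merge two gapped character matrices along an alignment path
.merge_profiles <- function(mat_a, mat_b, a_idx, b_idx) {
  n <- length(a_idx)
  out_a <- matrix("-", nrow(mat_a), n)
  out_b <- matrix("-", nrow(mat_b), n)
  sel_a <- a_idx > 0; sel_b <- b_idx > 0
  out_a[, sel_a] <- mat_a[, a_idx[sel_a], drop = FALSE]
  out_b[, sel_b] <- mat_b[, b_idx[sel_b], drop = FALSE]
  rbind(out_a, out_b)
}
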