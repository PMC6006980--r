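# Degenerate catalytic-motif patterns and the scanner used to validate
# alignment-anchored domain windows.
#
# Pattern syntax: fixed residue letters; "x" matches anything; "A/B"
# allows either residue at one position; "(x)" is an optional wildcard
# position (the pattern is tried with and without it). max_mismatch
# substitutions are tolerated at fixed (non-wildcard) positions.

#' Define a degenerate motif pattern
#'
#' @param name Motif name.
#' @param pattern Degenerate expression: fixed letters, `x` wildcards,
#'   `/`-separated alternatives, `(x)` optional wildcard positions.
#' @param max_mismatch Number of substitutions tolerated at fixed
#'   positions (must be smaller than the number of fixed positions).
#' @param diagnostic_index 0-based offset of the catalytic residue within
#'   the match, or `NA`. The special value `-1` marks the last position
#'   of the (possibly expanded) match.
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, pattern, max_mismatch = 0L,
                          diagnostic_index = NA_integer_) {
  toks <- .parse_motif(pattern)
  if (length(toks) < 3L) stop("motif_pattern: pattern length must be >= 3")
  n_fixed <- sum(vapply(toks, function(t) !t$optional && !t$wild, logical(1)))
  if (max_mismatch >= n_fixed)
    stop("motif_pattern: max_mismatch must be < number of fixed letters")
  structure(list(name = name, pattern = pattern, tokens = toks,
                 max_mismatch = as.integer(max_mismatch),
                 diagnostic_index = as.integer(diagnostic_index)),
            class = "motif_pattern")
}

.parse_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  toks <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (i + 2L > length(chars) || chars[i + 1L] != "x" || chars[i + 2L] != ")")
        stop("motif_pattern: malformed optional position in '", pattern, "'")
      toks[[length(toks) + 1L]] <- list(allowed = NULL, wild = TRUE,
                                        optional = TRUE)
      i <- i + 3L
    } else if (ch == "x") {
      toks[[length(toks) + 1L]] <- list(allowed = NULL, wild = TRUE,
                                        optional = FALSE)
      i <- i + 1L
    } else if (grepl("[A-WYZ]", ch)) {
      allowed <- ch; i <- i + 1L
      while (i + 1L <= length(chars) && chars[i] == "/") {
        allowed <- c(allowed, chars[i + 1L]); i <- i + 2L
      }
      toks[[length(toks) + 1L]] <- list(allowed = allowed, wild = FALSE,
                                        optional = FALSE)
    } else {
      stop("motif_pattern: unexpected character '", ch, "' in '", pattern, "'")
    }
  }
  toks
}

# concrete variants of a token list: every subset of optional positions
# dropped, longest variant first so longer matches win ties
.motif_variants <- function(tokens) {
  opt <- which(vapply(tokens, function(t) isTRUE(t$optional), logical(1)))
  if (!length(opt)) return(list(tokens))
  subsets <- list(integer(0))
  for (o in opt) subsets <- c(subsets, lapply(subsets, c, o))
  variants <- lapply(subsets, function(drop)
    if (length(drop)) tokens[-drop] else tokens)
  variants[order(vapply(variants, length, integer(1)), decreasing = TRUE)]
}

#' Scan a sequence for a degenerate motif
#'
#' Returns every position where the pattern matches with at most
#' `max_mismatch` substitutions at fixed positions. Wildcards match any
#' residue; optional `(x)` positions are tried both present and absent.
#'
#' @param sequence Uppercase amino-acid string.
#' @param pattern A [motif_pattern].
#' @return Data frame with columns `position` (0-based), `mismatches` and
#'   `length` (of the concrete match), sorted by position then mismatch
#'   count. Zero rows if there is no match.
#' @export
scan_motif <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  empty <- data.frame(position = integer(), mismatches = integer(),
                      length = integer())
  n <- nchar(sequence)
  if (n == 0L) return(empty)
  seq_chars <- strsplit(sequence, "")[[1]]
  out <- empty
  for (toks in .motif_variants(pattern$tokens)) {
    L <- length(toks)
    if (L > n) next
    starts <- seq_len(n - L + 1L)
    mism <- integer(length(starts))
    for (k in seq_len(L)) {
      t <- toks[[k]]
      if (t$wild) next
      mism <- mism + !(seq_chars[starts + k - 1L] %in% t$allowed)
    }
    ok <- mism <= pattern$max_mismatch
    if (any(ok)) {
      out <- rbind(out, data.frame(position = starts[ok] - 1L,
                                   mismatches = mism[ok], length = L))
    }
  }
  if (!nrow(out)) return(empty)
  out <- out[order(out$position, out$mismatches, -out$length), , drop = FALSE]
  out <- out[!duplicated(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catalytic-motif registry for PKS domains
#'
#' The motif set used to validate detected domains and read out
#' active-site residues: the ketosynthase catalytic triad (Cys plus two
#' His, the first Cys replaced by Gln in loading-module KSq), the ACP
#' phosphopantetheinylation serine motif `L/IG(x)DS`, the KR NADP(H)
#' binding motif and KSY catalytic triad, the DH consensus `HxxxGxxxP`,
#' the ER consensus `LxHxxxGGVGxxAxxxA`, and active-site motifs for AT
#' and TE. Sites read out by the variant callers (KS Cys/Gln, ACP Ser)
#' are wildcarded in the pattern so that substituted variants still
#' anchor, and the observed residue decides the call.
#'
#' @return Named list of lists of [motif_pattern] objects, keyed by
#'   domain type.
#' @export
pks_motifs <- function() {
  list(
    KS = list(
      motif_pattern("ks_cys",  "DTAxSSS", 0L, 3L),
      motif_pattern("ks_his1", "SAxGTGT", 0L, 2L),
      motif_pattern("ks_his2", "KSNIGxL", 0L, 5L)
    ),
    AT = list(motif_pattern("at_ser", "GHSQG", 0L, 2L)),
    DH = list(motif_pattern("dh_consensus", "HxxxGxxxP", 0L, 0L)),
    ER = list(motif_pattern("er_consensus", "LxHxxxGGVGxxAxxxA", 1L, 2L)),
    KR = list(
      motif_pattern("kr_nadph", "GxTGxLG", 0L, NA_integer_),
      motif_pattern("kr_triad", "KSY", 0L, 0L)
    ),
    ACP = list(motif_pattern("acp_ppant", "L/IG(x)Dx", 0L, -1L)),
    TE = list(motif_pattern("te_ser", "GWSxGG", 0L, 2L))
  )
}
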