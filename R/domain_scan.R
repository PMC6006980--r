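# Domain detection: candidate windows are anchored by local alignment of
# one exemplar per domain type against the protein (iterated with
# masking, stopping below a fraction of the exemplar self-score), then
# validated by catalytic-motif scanning inside each window. Overlaps are
# resolved greedily by descending alignment score (ties: leftmost).

.MOTIF_MARGIN <- 5L  # residues of slack around a window when validating

#' Detect PKS domains in a protein
#'
#' @param record A [protein_record] (or plain sequence string).
#' @param reference Output of [pks_reference()] (exemplar scaffolds).
#' @param window_threshold Candidate windows must score at least this
#'   fraction of the exemplar self-score (default 0.35).
#' @param motifs Motif registry, see [pks_motifs()].
#' @return Data frame of domain hits, one row per detected domain, in
#'   N-to-C order: `protein_id`, `domain_type` (KS/KSQ/AT/DH/ER/KR/ACP/
#'   TE), `start`/`end` (0-based half-open), `score`, `active`, `reason`
#'   (non-empty whenever `active` is `FALSE`), `motif_summary`.
#' @export
detect_domains <- function(record, reference = pks_reference(),
                           window_threshold = 0.35, motifs = pks_motifs()) {
  if (is.character(record)) record <- protein_record("query", record)
  seq <- record$sequence
  n <- nchar(seq)
  scaffolds <- reference$scaffolds
  empty <- data.frame(protein_id = character(), domain_type = character(),
                      start = integer(), end = integer(), score = numeric(),
                      active = logical(), reason = character(),
                      motif_summary = character())
  if (n < min(nchar(scaffolds))) {
    warning("detect_domains: protein '", record$id,
            "' shorter than the smallest exemplar; no domains reported")
    return(empty)
  }
  windows <- empty[0, c("domain_type", "start", "end", "score")]
  for (type in names(scaffolds)) {
    exemplar <- scaffolds[[type]]
    min_score <- window_threshold * .self_score(exemplar)
    mask <- integer()
    repeat {
      hit <- local_align(exemplar, seq, mask = mask)
      if (hit$score < min_score || hit$b_range[1] == 0L) break
      windows <- rbind(windows,
                       data.frame(domain_type = type,
                                  start = hit$b_range[1] - 1L,
                                  end = hit$b_range[2],
                                  score = hit$score))
      mask <- c(mask, hit$b_range[1]:hit$b_range[2])
    }
  }
  if (!nrow(windows)) return(empty)
  # greedy non-overlap by descending score, ties leftmost
  windows <- windows[order(-windows$score, windows$start), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    span <- (windows$start[i] + 1L):windows$end[i]
    if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
  }
  windows <- windows[keep, , drop = FALSE]
  windows <- windows[order(windows$start), , drop = FALSE]

  hits <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    .validate_window(record$id, seq, w$domain_type, w$start, w$end, w$score,
                     motifs)
  }))
  rownames(hits) <- NULL
  hits
}

# validate one window: scan the type's motifs, set active status, and
# retype KS -> KSQ from the triad residue
.validate_window <- function(protein_id, seq, type, start, end, score,
                             motifs) {
  lo <- max(0L, start - .MOTIF_MARGIN)
  hi <- min(nchar(seq), end + .MOTIF_MARGIN)
  region <- substr(seq, lo + 1L, hi)
  found <- list()
  for (mp in motifs[[type]]) {
    m <- scan_motif(region, mp)
    found[[mp$name]] <- if (nrow(m)) {
      m$position <- m$position + lo  # absolute 0-based
      m[1, , drop = FALSE]
    } else NULL
  }
  missing <- names(motifs[[type]])[vapply(motifs[[type]], function(mp)
    is.null(found[[mp$name]]), logical(1))]
  names(missing) <- NULL
  active <- TRUE; reason <- ""
  out_type <- type
  if (length(missing)) {
    active <- FALSE
    reason <- paste0("motif_missing:", paste(missing, collapse = ","))
  }
  summary <- paste(vapply(names(found), function(nm)
    sprintf("%s@%d", nm, found[[nm]]$position), character(1)),
    collapse = ";")
  hit <- data.frame(protein_id = protein_id, domain_type = out_type,
                    start = start, end = end, score = score,
                    active = active, reason = reason,
                    motif_summary = summary)
  if (type == "KS") {
    ks <- call_ks_variant(hit, seq, motifs)
    hit$domain_type <- ks$domain_type
    hit$active <- ks$active
    hit$reason <- ks$reason
  } else if (type == "ACP") {
    ok <- call_acp(hit, seq, motifs)
    hit$active <- ok
    if (!ok && hit$reason == "") hit$reason <- "ppant_ser_missing"
  }
  hit
}

#' Classify a ketosynthase hit as KS or KSq
#'
#' Reads the catalytic triad: the first triad residue decides the call
#' (Cys = condensing KS; Gln = decarboxylating loading-module KSq;
#' anything else = KS with `active = FALSE`). The two His positions must
#' be His (the second may be Asn). An unlocatable triad yields an
#' inactive KS with reason `triad_missing`.
#'
#' @param hit One row of a domain-hit data frame with `domain_type`
#'   `"KS"`.
#' @param sequence Full protein sequence the hit refers to.
#' @param motifs Motif registry.
#' @return List with `domain_type` (`"KS"` or `"KSQ"`), `active`,
#'   `reason` and `triad` (the three observed residues, or `NA`).
#' @export
call_ks_variant <- function(hit, sequence, motifs = pks_motifs()) {
  stopifnot(hit$domain_type %in% c("KS", "KSQ"))
  lo <- max(0L, hit$start - .MOTIF_MARGIN)
  hi <- min(nchar(sequence), hit$end + .MOTIF_MARGIN)
  region <- substr(sequence, lo + 1L, hi)
  triad <- rep(NA_character_, 3L)
  for (k in 1:3) {
    mp <- motifs$KS[[k]]
    m <- scan_motif(region, mp)
    if (nrow(m))
      triad[k] <- substr(region, m$position[1] + mp$diagnostic_index + 1L,
                         m$position[1] + mp$diagnostic_index + 1L)
  }
  if (anyNA(triad)) {
    return(list(domain_type = "KS", active = FALSE, reason = "triad_missing",
                triad = triad))
  }
  his_ok <- triad[2] == "H" && triad[3] %in% c("H", "N")
  if (triad[1] == "Q" && his_ok)
    return(list(domain_type = "KSQ", active = TRUE, reason = "",
                triad = triad))
  if (triad[1] == "C" && his_ok)
    return(list(domain_type = "KS", active = TRUE, reason = "",
                triad = triad))
  list(domain_type = "KS", active = FALSE, reason = "triad_substituted",
       triad = triad)
}

#' Check the ACP phosphopantetheinylation serine
#'
#' `TRUE` iff the conserved L/IG(x)DS motif is present in the hit region
#' with serine at the phosphopantetheine attachment position.
#'
#' @param hit One row of a domain-hit data frame with `domain_type`
#'   `"ACP"`.
#' @param sequence Full protein sequence.
#' @param motifs Motif registry.
#' @return Logical.
#' @export
call_acp <- function(hit, sequence, motifs = pks_motifs()) {
  lo <- max(0L, hit$start - .MOTIF_MARGIN)
  hi <- min(nchar(sequence), hit$end + .MOTIF_MARGIN)
  region <- substr(sequence, lo + 1L, hi)
  mp <- motifs$ACP[[1]]
  m <- scan_motif(region, mp)
  if (!nrow(m)) return(FALSE)
  ser_pos <- m$position[1] + m$length[1]  # 1-based index of last match char
  substr(region, ser_pos, ser_pos) == "S"
}
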