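# Functional subtype calls: AT extender-unit specificity (diagnostic
# residues and/or phylogenetic placement), KR stereo-type (A/B via
# Trp and LDD/LED signatures), and DH/ER functionality flags.

# map 0-based scaffold positions to 1-based query positions through a
# global alignment of scaffold (a) vs query (b); 0 where the query gaps
.map_positions <- function(scaffold, query, positions0) {
  al <- pairwise_align(scaffold, query)
  vapply(positions0, function(p0) {
    k <- which(al$a_idx == p0 + 1L)
    if (!length(k)) return(0L)
    al$b_idx[k[1]]
  }, integer(1))
}

#' Classify a ketoreductase region as A-type or B-type
#'
#' Aligns the KR region to the packaged KR reference and inspects the
#' B-type diagnostic window (LDD, or the LED variant) and the A-type
#' diagnostic position (Trp). B-type KRs produce R-configured alcohols,
#' A-type S-configured ones; a region with neither signature is
#' unassigned and its product configuration unknown. Both signatures
#' present yields `unassigned` with a conflict flag.
#'
#' @param region KR amino-acid sequence (the detected hit interval).
#' @param reference Output of [pks_reference()].
#' @return List of class `kr_call`: `stereo_type` (`"A"`, `"B"`,
#'   `"unassigned"`), `signature` (`"LDD"`, `"LED"`, `"TRP"`, `"none"`),
#'   `predicted_oh_config` (`"R"`, `"S"`, `"unknown"`), `conflict`,
#'   `reason`.
#' @export
classify_kr <- function(region, reference = pks_reference()) {
  out <- function(st, sig, cfg, conflict = FALSE, reason = "") {
    structure(list(stereo_type = st, signature = sig,
                   predicted_oh_config = cfg, conflict = conflict,
                   reason = reason), class = "kr_call")
  }
  region <- toupper(if (inherits(region, "protein_record"))
    region$sequence else region)
  scaffold <- reference$scaffolds[["KR"]]
  if (nchar(region) < nchar(scaffold) / 3)
    return(out("unassigned", "none", "unknown",
               reason = "region_too_short"))
  bwin <- .site(reference$sites, "KR", "kr_b_window")
  asite <- .site(reference$sites, "KR", "kr_a_site")
  pos <- .map_positions(scaffold, region,
                        c(bwin$start + 0:(bwin$length - 1), asite$start))
  bq <- pos[1:3]; aq <- pos[4]
  b_res <- if (all(bq > 0)) paste(substring(region, bq, bq), collapse = "")
           else ""
  a_res <- if (aq > 0) substr(region, aq, aq) else ""
  b_hit <- b_res %in% c("LDD", "LED")
  a_hit <- identical(a_res, "W")
  if (b_hit && a_hit) return(out("unassigned", "none", "unknown",
                                 conflict = TRUE,
                                 reason = "conflicting_signatures"))
  if (b_hit) return(out("B", b_res, "R"))
  if (a_hit) return(out("A", "TRP", "S"))
  out("unassigned", "none", "unknown")
}

.new_at_call <- function(specificity, confidence = 0,
                         residue_evidence = NULL, tree_support = NA_real_,
                         discordant = FALSE, method = "residues",
                         reason = "") {
  structure(list(specificity = specificity, confidence = confidence,
                 residue_evidence = residue_evidence,
                 tree_support = tree_support, discordant = discordant,
                 method = method, reason = reason), class = "at_call")
}

#' Classify AT extender-unit specificity by diagnostic residues
#'
#' Aligns the AT region to the panel anchor scaffold, reads the residues
#' at the annotated specificity-determining columns and takes a majority
#' vote across columns (malonyl-CoA vs methylmalonyl-CoA). Confidence is
#' the fraction of diagnostic columns agreeing with the winning class.
#'
#' @param region AT amino-acid sequence.
#' @param reference Output of [pks_reference()] (scaffold anchor +
#'   annotated columns).
#' @return List of class `at_call`: `specificity` (`"malonyl"`,
#'   `"methylmalonyl"`, `"unknown"`), `confidence` in `[0, 1]`,
#'   `residue_evidence` data frame, `tree_support` (`NA` here),
#'   `discordant`, `method`.
#' @export
classify_at_residues <- function(region, reference = pks_reference()) {
  region <- toupper(if (inherits(region, "protein_record"))
    region$sequence else region)
  sites <- reference$sites
  diag <- sites[sites$domain == "AT" & !is.na(sites$expected_malonyl), ]
  scaffold <- reference$scaffolds[["AT"]]
  pos <- .map_positions(scaffold, region, diag$start)
  gaps <- pos == 0L
  if (mean(gaps) > 0.5)
    return(.new_at_call("unknown", reason = "diagnostic_columns_in_gaps"))
  obs <- ifelse(gaps, NA, substring(region, pos, pos))
  ev <- data.frame(column = diag$site, position = pos, observed = obs,
                   expected_malonyl = diag$expected_malonyl,
                   expected_methylmalonyl = diag$expected_methylmalonyl)
  v_mal <- sum(obs == diag$expected_malonyl, na.rm = TRUE)
  v_mm <- sum(obs == diag$expected_methylmalonyl, na.rm = TRUE)
  n_cols <- nrow(diag)
  if (v_mal == v_mm)
    return(.new_at_call("unknown", confidence = 0, residue_evidence = ev,
                        reason = if (v_mal == 0) "no_diagnostic_match"
                                 else "tied_vote"))
  win <- if (v_mal > v_mm) "malonyl" else "methylmalonyl"
  .new_at_call(win, confidence = max(v_mal, v_mm) / n_cols,
               residue_evidence = ev)
}

#' Classify AT specificity by phylogenetic placement
#'
#' Builds a neighbor-joining tree over the query plus the reference
#' panel; the call is the class of the smallest monophyletic group of
#' same-class panel members that contains the query, with the bootstrap
#' support of the subtending branch (when `n_bootstrap >= 1`).
#'
#' @param region AT amino-acid sequence.
#' @param panel Output of [pks_at_panel()].
#' @param n_bootstrap Bootstrap replicates for the support value (0 to
#'   skip).
#' @param seed Seed for the bootstrap resampling.
#' @return An `at_call` with `method = "phylogeny"`; `specificity` is
#'   `"unknown"` when the query sits basal to all classes.
#' @export
classify_at_phylo <- function(region, panel = pks_at_panel(),
                              n_bootstrap = 0L, seed = 1L) {
  region <- toupper(if (inherits(region, "protein_record"))
    region$sequence else region)
  recs <- c(list(protein_record("query", region)), panel$records)
  aln <- progressive_msa(recs)
  D <- p_distance(aln)
  tree <- nj_tree(D)
  sides <- .query_sides(tree, "query")
  cands <- list()
  for (s in sides) {
    members <- setdiff(s$tips, "query")
    if (!length(members)) next
    cls <- unique(panel$classes[members])
    if (length(cls) != 1L || anyNA(cls)) next
    cands[[length(cands) + 1L]] <- list(class = cls,
                                        size = length(s$tips),
                                        node = s$node, tips = s$tips)
  }
  if (!length(cands))
    return(.new_at_call("unknown", method = "phylogeny",
                        reason = "basal_placement"))
  sizes <- vapply(cands, `[[`, numeric(1), "size")
  minimal <- cands[sizes == min(sizes)]
  min_classes <- unique(vapply(minimal, `[[`, character(1), "class"))
  if (length(min_classes) > 1L) {
    # query sits on the edge between the classes (e.g. at the root
    # trifurcation); resolve by mean distance to each tied side's
    # members, staying unknown when equidistant
    mean_d <- vapply(minimal, function(s)
      mean(D["query", setdiff(s$tips, "query")]), numeric(1))
    if (abs(diff(range(mean_d))) < 1e-9)
      return(.new_at_call("unknown", method = "phylogeny",
                          reason = "basal_placement"))
    minimal <- minimal[order(mean_d)]
  }
  best <- minimal[[1]]
  support <- NA_real_
  if (n_bootstrap >= 1L) {
    bt <- bootstrap_tree(aln, n_replicates = n_bootstrap, seed = seed)
    support <- unname(bt$node.label[best$node - length(bt$tip.label)])
  }
  .new_at_call(best$class, confidence = 1, tree_support = support,
               method = "phylogeny")
}

# all bipartition sides of an unrooted tree that contain `query`;
# each side is reported with the internal node defining its edge
.query_sides <- function(tree, query) {
  tips <- tree$tip.label
  parts <- ape::prop.part(tree)
  sides <- list()
  for (k in seq_along(parts)) {
    clade <- tips[parts[[k]]]
    node <- length(tips) + k
    if (k == 1L) next  # root partition: trivial (all tips)
    comp <- setdiff(tips, clade)
    if (query %in% clade)
      sides[[length(sides) + 1L]] <- list(tips = clade, node = node)
    else
      sides[[length(sides) + 1L]] <- list(tips = comp, node = node)
  }
  sides
}

#' Combined AT specificity call
#'
#' Runs the residue-based and (optionally) the phylogeny-based
#' classifiers and combines them. When the two disagree the specificity
#' follows `precedence` (default: residues) and the call is flagged
#' discordant, with both lines of evidence retained.
#'
#' @inheritParams classify_at_residues
#' @inheritParams classify_at_phylo
#' @param use_phylo Run the phylogenetic classifier as well.
#' @param precedence `"residues"` or `"phylogeny"`: which call wins on
#'   disagreement.
#' @return An `at_call` with `method = "combined"` (or the single method
#'   used) and a `phylo_call` element holding the secondary evidence.
#' @export
classify_at <- function(region, reference = pks_reference(),
                        panel = pks_at_panel(), use_phylo = TRUE,
                        precedence = c("residues", "phylogeny"),
                        n_bootstrap = 0L, seed = 1L) {
  precedence <- match.arg(precedence)
  res <- classify_at_residues(region, reference)
  if (!use_phylo) return(res)
  phy <- classify_at_phylo(region, panel, n_bootstrap, seed)
  call <- res
  call$tree_support <- phy$tree_support
  call$phylo_call <- phy
  call$method <- "combined"
  if (res$specificity == "unknown" && phy$specificity != "unknown") {
    call$specificity <- phy$specificity
    call$confidence <- phy$confidence
  } else if (phy$specificity != "unknown" &&
             res$specificity != phy$specificity) {
    call$discordant <- TRUE
    if (precedence == "phylogeny") {
      call$specificity <- phy$specificity
      call$confidence <- phy$confidence
    }
  }
  call
}

#' DH/ER functionality of one module
#'
#' A module's dehydratase is functional iff a DH hit with the intact
#' consensus motif is present; the enoylreductase flag is set iff an
#' active ER hit is present.
#'
#' @param module_domains Data frame of the module's domain hits.
#' @return List `(dh_functional, er_present)`.
#' @export
call_dh_er_functionality <- function(module_domains) {
  d <- module_domains
  list(dh_functional = any(d$domain_type == "DH" & d$active),
       er_present = any(d$domain_type == "ER" & d$active))
}

#' @export
print.at_call <- function(x, ...) {
  cat(sprintf("<at_call> %s (confidence %.2f%s%s, %s)\n", x$specificity,
              x$confidence,
              if (is.na(x$tree_support)) ""
              else sprintf(", bootstrap %.0f%%", x$tree_support),
              if (x$discordant) ", DISCORDANT" else "", x$method))
  invisible(x)
}

#' @export
print.kr_call <- function(x, ...) {
  cat(sprintf("<kr_call> %s-type (signature %s) -> %s hydroxyl%s\n",
              x$stereo_type, x$signature, x$predicted_oh_config,
              if (x$conflict) " [conflict]" else ""))
  invisible(x)
}
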