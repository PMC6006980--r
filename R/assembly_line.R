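# Module partitioning and the colinearity rule.
#
# Carbon numbering follows the chemistry convention: C1 is the carbonyl
# carbon delivered to the thioesterase, so for N extension modules the
# backbone has 2(N+1) carbons and module m (1..N) contributes the
# alpha/beta carbon pair C(2N+2-2m)/C(2N+3-2m). Consequences used
# throughout:
#   * the hydroxyl installed by module m's KR sits at carbon 2N+3-2m,
#   * a methylmalonyl-specific AT at module m puts a methyl branch at
#     carbon 2N+2-2m,
#   * a functional DH at module m (acting on the R-configured product of
#     a B-type KR, syn elimination) draws an E double bond at
#     delta(2N+2-2m), consuming the hydroxyl.

#' Build an assembly line from ordered domain hits
#'
#' Cuts the concatenated domain string into modules at each KS (or KSq)
#' boundary: domains between consecutive ketosynthases belong to the
#' left module, domains before the first KS attach to the loading
#' module. Module indices run 0 (loading) .. N contiguously across ORFs
#' in ORF order. Grammar violations (extension module without KS+AT+ACP,
#' orphan leading domains) are logged in
#' `attr(line, "grammar_violations")`, not fatal.
#'
#' @param hits_by_orf Named list of domain-hit data frames (from
#'   [detect_domains()]), each in N-to-C order.
#' @param orf_order Character vector giving cluster order of the ORFs;
#'   defaults to the list names in order.
#' @return Object of class `assembly_line` with elements `modules` (list
#'   of module models) and `te_present`.
#' @export
build_assembly_line <- function(hits_by_orf, orf_order = names(hits_by_orf)) {
  stopifnot(is.list(hits_by_orf), length(orf_order) >= 1L,
            all(orf_order %in% names(hits_by_orf)))
  violations <- character()
  all_hits <- do.call(rbind, lapply(orf_order, function(orf) {
    h <- as.data.frame(hits_by_orf[[orf]])
    if (nrow(h)) h$source_orf <- orf
    h
  }))
  if (is.null(all_hits) || !nrow(all_hits))
    stop("build_assembly_line: no modules detectable (no hits)")
  ks_idx <- which(all_hits$domain_type %in% c("KS", "KSQ"))
  if (!length(ks_idx))
    stop("build_assembly_line: no modules detectable (no KS/KSq hit)")
  if (ks_idx[1] > 1L)
    violations <- c(violations,
                    sprintf("orphan domains before first KS (%s) attached to loading module",
                            paste(all_hits$domain_type[seq_len(ks_idx[1] - 1L)],
                                  collapse = ",")))
  bounds <- c(ks_idx, nrow(all_hits) + 1L)
  te_present <- FALSE
  modules <- list()
  for (m in seq_along(ks_idx)) {
    rows <- if (m == 1L) seq_len(bounds[2] - 1L)
            else bounds[m]:(bounds[m + 1L] - 1L)
    dom <- all_hits[rows, , drop = FALSE]
    te_rows <- dom$domain_type == "TE"
    if (any(te_rows)) {
      if (m == length(ks_idx)) te_present <- TRUE
      else violations <- c(violations,
                           sprintf("TE inside internal module %d", m - 1L))
      dom <- dom[!te_rows, , drop = FALSE]
    }
    idx <- m - 1L
    if (idx == 0L) {
      if (!any(dom$domain_type == "KSQ"))
        violations <- c(violations,
                        "loading module lacks a KSq (or dedicated loading AT)")
    } else {
      need <- c("KS", "AT", "ACP")
      miss <- setdiff(need, dom$domain_type)
      if (length(miss))
        violations <- c(violations,
                        sprintf("extension module %d lacks %s", idx,
                                paste(miss, collapse = "+")))
    }
    modules[[m]] <- structure(
      list(index = idx, domains = dom, at_call = NULL, kr_call = NULL,
           dh_functional = FALSE, er_present = FALSE,
           source_orf = dom$source_orf[1]),
      class = "module_model")
  }
  structure(list(modules = modules, te_present = te_present),
            class = "assembly_line",
            grammar_violations = violations)
}

#' Attach functional classifications to an assembly line
#'
#' For every module, extracts the AT and KR regions from the source
#' proteins and runs the specificity/stereo-type classifiers plus the
#' DH/ER functionality check.
#'
#' @param line An `assembly_line` from [build_assembly_line()].
#' @param records List of [protein_record] objects covering every
#'   `source_orf` in the line.
#' @param reference,panel Packaged reference data.
#' @param use_phylo Also run the phylogenetic AT classifier.
#' @param precedence AT precedence on discordance (see [classify_at()]).
#' @param n_bootstrap,seed Bootstrap settings for AT tree support.
#' @return The line with `at_call`, `kr_call`, `dh_functional` and
#'   `er_present` filled in on every module.
#' @export
annotate_assembly_line <- function(line, records,
                                   reference = pks_reference(),
                                   panel = pks_at_panel(),
                                   use_phylo = TRUE,
                                   precedence = "residues",
                                   n_bootstrap = 0L, seed = 1L) {
  seqs <- stats::setNames(vapply(records, function(r) r$sequence,
                                 character(1)),
                          vapply(records, function(r) r$id, character(1)))
  region_of <- function(dom, type) {
    row <- dom[dom$domain_type == type, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    substr(seqs[[row$protein_id[1]]], row$start[1] + 1L, row$end[1])
  }
  line$modules <- lapply(line$modules, function(mod) {
    at_region <- region_of(mod$domains, "AT")
    if (!is.null(at_region))
      mod$at_call <- classify_at(at_region, reference, panel,
                                 use_phylo = use_phylo,
                                 precedence = precedence,
                                 n_bootstrap = n_bootstrap, seed = seed)
    kr_region <- region_of(mod$domains, "KR")
    if (!is.null(kr_region))
      mod$kr_call <- classify_kr(kr_region, reference)
    fn <- call_dh_er_functionality(mod$domains)
    mod$dh_functional <- fn$dh_functional
    mod$er_present <- fn$er_present
    mod
  })
  line
}

#' @export
print.assembly_line <- function(x, ...) {
  n_ext <- length(x$modules) - 1L
  cat(sprintf("<assembly_line> %d modules (loading + %d extension), TE %s\n",
              length(x$modules), n_ext,
              if (x$te_present) "present" else "absent"))
  for (mod in x$modules) {
    cat(sprintf("  module %2d [%s]: %s%s%s%s\n", mod$index,
                ifelse(is.na(mod$source_orf), "?", mod$source_orf),
                paste(mod$domains$domain_type, collapse = "-"),
                if (!is.null(mod$at_call))
                  paste0("  AT=", mod$at_call$specificity) else "",
                if (!is.null(mod$kr_call))
                  paste0("  KR=", mod$kr_call$stereo_type) else "",
                if (mod$dh_functional) "  DH+" else ""))
  }
  invisible(x)
}

.at_specificity <- function(mod) {
  if (is.null(mod$at_call)) "unknown" else mod$at_call$specificity
}

#' Predict the backbone chemotype by the colinearity rule
#'
#' Walks the extension modules and assigns one state per beta carbon:
#' no (active) KR leaves a ketone; A-type KR gives an S-configured and
#' B-type an R-configured hydroxyl (unassigned: unknown configuration);
#' a functional DH performs syn elimination on the R-configured hydroxyl
#' to give an E-configured double bond (a DH over a non-R hydroxyl is
#' flagged and no bond is drawn; DH without KR is flagged and the carbon
#' stays keto); DH plus ER reduces through to methylene. Methylmalonyl
#' ATs add methyl branches; the loading KSq decarboxylates its unit, so
#' a malonyl loading AT gives an acetate starter and a methylmalonyl one
#' propionate.
#'
#' @param line An annotated `assembly_line`.
#' @return Object of class `chemotype_table`: `carbon_count` (=
#'   2(N+1)), `states` (data frame `carbon`, `state`, `module` over the
#'   beta carbons; states `keto`, `OH_R`, `OH_S`, `OH_unknown`,
#'   `enoyl_E`, `methylene`), `double_bonds`, `methyl_branches`,
#'   `starter_unit`, `flags`, `ring_closure` (`NA` unless configured).
#' @export
predict_chemotype <- function(line) {
  stopifnot(inherits(line, "assembly_line"))
  N <- length(line$modules) - 1L
  if (N < 1L) stop("predict_chemotype: no extension modules")
  carbon_count <- 2L * (N + 1L)
  states <- data.frame(carbon = integer(), state = character(),
                       module = integer())
  bonds <- data.frame(delta = integer(), geometry = character(),
                      module = integer())
  methyls <- integer(); flags <- character()
  for (mod in line$modules) {
    m <- mod$index
    if (m == 0L) next
    beta <- 2L * N + 3L - 2L * m
    alpha <- beta - 1L
    kr <- mod$kr_call
    state <- if (is.null(kr) || kr$stereo_type == "absent") "keto"
             else switch(kr$stereo_type,
                         A = "OH_S", B = "OH_R", unassigned = "OH_unknown",
                         "keto")
    if (mod$dh_functional) {
      if (is.null(kr)) {
        flags <- c(flags, sprintf("module %d: DH without KR; state kept keto",
                                  m))
      } else if (state == "OH_R") {
        state <- "enoyl_E"
        bonds <- rbind(bonds, data.frame(delta = alpha, geometry = "E",
                                         module = m))
        if (mod$er_present) {
          state <- "methylene"
          bonds <- bonds[bonds$module != m, , drop = FALSE]
        }
      } else {
        flags <- c(flags,
                   sprintf("module %d: DH over %s; no bond drawn", m, state))
      }
    }
    states <- rbind(states, data.frame(carbon = beta, state = state,
                                       module = m))
    if (.at_specificity(mod) == "methylmalonyl")
      methyls <- c(methyls, alpha)
  }
  starter <- switch(.at_specificity(line$modules[[1]]),
                    malonyl = "acetate", methylmalonyl = "propionate",
                    "acetate")
  states <- states[order(states$carbon), , drop = FALSE]
  rownames(states) <- NULL
  structure(list(carbon_count = carbon_count, states = states,
                 double_bonds = bonds[order(bonds$delta), , drop = FALSE],
                 methyl_branches = sort(methyls), starter_unit = starter,
                 flags = flags, ring_closure = NA_integer_),
            class = "chemotype_table")
}

#' @export
print.chemotype_table <- function(x, ...) {
  cat(sprintf("<chemotype_table> C%d backbone, starter %s\n",
              x$carbon_count, x$starter_unit))
  oh <- x$states[grepl("^OH", x$states$state), ]
  cat(sprintf("  hydroxyls: %s\n",
              paste(sprintf("C%d(%s)", oh$carbon,
                            sub("OH_", "", oh$state)), collapse = " ")))
  cat(sprintf("  E double bonds: %s\n",
              paste0("Δ", x$double_bonds$delta, collapse = " ")))
  cat(sprintf("  methyl branches: %s\n",
              paste0("C", x$methyl_branches, collapse = " ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Encode a predicted chemotype as an observed one
#'
#' Utility for round-trips and self-consistency checks: converts a
#' [predict_chemotype()] table into the [observed_chemotype()] encoding
#' (OH_R -> R and so on; keto/methylene carbons carry no entry).
#'
#' @param ct A `chemotype_table`.
#' @return An `observed_chemotype`.
#' @export
chemotype_as_observed <- function(ct) {
  oh <- ct$states[grepl("^OH", ct$states$state), ]
  observed_chemotype(
    carbon_count = ct$carbon_count,
    hydroxyls = data.frame(carbon = oh$carbon,
                           config = sub("OH_", "", oh$state)),
    double_bonds = ct$double_bonds[, c("delta", "geometry")],
    methyl_branches = ct$methyl_branches,
    starter_unit = ct$starter_unit)
}

#' Reconcile a predicted chemotype against an observed structure
#'
#' Compares starter unit, methyl-branch set, per-position hydroxyl
#' presence/configuration (unknown configurations match anything) and
#' the double-bond set; every mismatch is mapped back to the responsible
#' module and categorized (`at_specificity`, `dh_skip`, `kr_config`,
#' `other`). A predicted double bond that the structure lacks counts as
#' a single `dh_skip` for its module (the consumed hydroxyl is not
#' double-counted). A carbon-count mismatch short-circuits into one
#' fatal `other` discrepancy.
#'
#' @param predicted A `chemotype_table`.
#' @param observed An `observed_chemotype`.
#' @return Data frame with columns `module_index`, `category`,
#'   `predicted`, `observed`; zero rows when fully consistent.
#' @export
reconcile <- function(predicted, observed) {
  stopifnot(inherits(predicted, "chemotype_table"),
            inherits(observed, "observed_chemotype"))
  disc <- data.frame(module_index = integer(), category = character(),
                     predicted = character(), observed = character())
  add <- function(module, category, pred, obs) {
    disc[nrow(disc) + 1L, ] <<- list(module, category, pred, obs)
  }
  if (predicted$carbon_count != observed$carbon_count) {
    add(NA_integer_, "other",
        sprintf("carbon_count=%d", predicted$carbon_count),
        sprintf("carbon_count=%d", observed$carbon_count))
    return(disc)
  }
  N <- predicted$carbon_count / 2L - 1L
  mod_of_beta <- function(c) as.integer((2L * N + 3L - c) / 2L)
  mod_of_alpha <- function(c) as.integer((2L * N + 2L - c) / 2L)

  if (predicted$starter_unit != observed$starter_unit)
    add(0L, "at_specificity", predicted$starter_unit, observed$starter_unit)

  for (c in setdiff(predicted$methyl_branches, observed$methyl_branches))
    add(mod_of_alpha(c), "at_specificity",
        sprintf("methyl at C%d", c), "no methyl")
  for (c in setdiff(observed$methyl_branches, predicted$methyl_branches))
    add(mod_of_alpha(c), "at_specificity",
        "no methyl", sprintf("methyl at C%d", c))

  pred_d <- predicted$double_bonds$delta
  obs_d <- observed$double_bonds$delta
  bond_flagged <- integer()
  for (d in setdiff(pred_d, obs_d)) {
    m <- mod_of_alpha(d)
    obs_state <- if ((d + 1L) %in% observed$hydroxyls$carbon)
      sprintf("OH at C%d", d + 1L) else "saturated"
    add(m, "dh_skip", sprintf("enoyl_E at Δ%d", d), obs_state)
    bond_flagged <- c(bond_flagged, d + 1L)
  }
  for (d in setdiff(obs_d, pred_d)) {
    m <- mod_of_alpha(d)
    pred_state <- predicted$states$state[predicted$states$carbon == d + 1L]
    add(m, "dh_skip",
        if (length(pred_state)) sprintf("%s at C%d", pred_state, d + 1L)
        else "saturated",
        sprintf("bond at Δ%d", d))
    bond_flagged <- c(bond_flagged, d + 1L)
  }
  # geometry disagreement on shared bonds
  both <- intersect(pred_d, obs_d)
  for (d in both) {
    pg <- predicted$double_bonds$geometry[pred_d == d][1]
    og <- observed$double_bonds$geometry[obs_d == d][1]
    if (pg != og)
      add(mod_of_alpha(d), "other", sprintf("Δ%d %s", d, pg),
          sprintf("Δ%d %s", d, og))
  }

  # hydroxyl comparison over beta carbons not already explained by a
  # bond discrepancy; an observed bond consumes the position too
  obs_oh <- observed$hydroxyls
  consumed_obs <- obs_d + 1L
  for (i in seq_len(nrow(predicted$states))) {
    c <- predicted$states$carbon[i]
    st <- predicted$states$state[i]
    if (c %in% bond_flagged) next
    pred_has <- grepl("^OH", st)
    obs_row <- obs_oh[obs_oh$carbon == c, , drop = FALSE]
    obs_has <- nrow(obs_row) > 0L
    if (st == "enoyl_E" || c %in% consumed_obs) next  # matched via bonds
    if (pred_has && obs_has) {
      pc <- sub("OH_", "", st); oc <- obs_row$config[1]
      if (pc != "unknown" && oc != "unknown" && pc != oc)
        add(mod_of_beta(c), "kr_config", sprintf("OH %s at C%d", pc, c),
            sprintf("OH %s at C%d", oc, c))
    } else if (pred_has && !obs_has) {
      add(mod_of_beta(c), "kr_config", sprintf("%s at C%d", st, c),
          sprintf("no OH at C%d", c))
    } else if (!pred_has && obs_has) {
      add(mod_of_beta(c), "kr_config", sprintf("%s at C%d", st, c),
          sprintf("OH at C%d", c))
    }
  }
  disc
}

#' Apply reconciliation results back onto an assembly line
#'
#' Turns `dh_skip` discrepancies into DH-inactive overrides and a
#' loading-module `at_specificity` discrepancy into the
#' structure-consistent AT call, so the chemotype can be regenerated
#' (predict, compare, annotate skip -- the skip is never inferred de
#' novo).
#'
#' @param line An annotated `assembly_line`.
#' @param discrepancies Output of [reconcile()].
#' @return The modified line.
#' @export
apply_reconciliation <- function(line, discrepancies) {
  for (i in seq_len(nrow(discrepancies))) {
    d <- discrepancies[i, ]
    if (is.na(d$module_index)) next
    mi <- d$module_index + 1L
    if (d$category == "dh_skip" && grepl("^enoyl_E", d$predicted)) {
      line$modules[[mi]]$dh_functional <- FALSE
      line$modules[[mi]]$dh_skipped <- TRUE
    } else if (d$category == "at_specificity" && d$module_index == 0L &&
               d$observed %in% c("acetate", "propionate")) {
      new_spec <- if (d$observed == "acetate") "malonyl" else "methylmalonyl"
      if (is.null(line$modules[[mi]]$at_call))
        line$modules[[mi]]$at_call <- .new_at_call(new_spec)
      else {
        line$modules[[mi]]$at_call$specificity <- new_spec
        line$modules[[mi]]$at_call$discordant <- TRUE
      }
    }
  }
  line
}

#' Fold change between two titers
#'
#' Ratio of two production means (e.g. mg/L of product in an engineered
#' strain versus the wild type), reported with two decimals.
#'
#' @param mean_a,mean_b Positive means.
#' @return `mean_a / mean_b` rounded to 2 decimals.
#' @export
titer_fold_change <- function(mean_a, mean_b) {
  if (!is.numeric(mean_a) || !is.numeric(mean_b) ||
      any(mean_a <= 0) || any(mean_b <= 0))
    stop("titer_fold_change: means must be positive")
  round(mean_a / mean_b, 2)
}

# ---- serialization -----------------------------------------------------

.line_summary_df <- function(line) {
  do.call(rbind, lapply(line$modules, function(mod) {
    data.frame(index = mod$index,
               source_orf = ifelse(is.na(mod$source_orf), "",
                                   mod$source_orf),
               domains = paste(mod$domains$domain_type, collapse = "-"),
               at_specificity = .at_specificity(mod),
               at_discordant = !is.null(mod$at_call) &&
                 isTRUE(mod$at_call$discordant),
               kr_type = if (is.null(mod$kr_call)) "absent"
                         else mod$kr_call$stereo_type,
               kr_signature = if (is.null(mod$kr_call)) "none"
                              else mod$kr_call$signature,
               dh_functional = mod$dh_functional,
               er_present = mod$er_present)
  }))
}

#' Serialize / deserialize an assembly line as JSON
#'
#' The JSON form carries the module summary (index, ORF, domain string,
#' AT and KR calls, DH/ER flags) and the TE flag; reading it back
#' reconstructs an `assembly_line` whose summary is identical.
#'
#' @param line An `assembly_line`.
#' @param path File path.
#' @param config Optional config list echoed into the file.
#' @return `write_assembly_json` returns `path` invisibly;
#'   `read_assembly_json` returns an `assembly_line`.
#' @export
write_assembly_json <- function(line, path, config = NULL) {
  out <- list(te_present = line$te_present, modules = .line_summary_df(line))
  if (length(config)) out$config <- config
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_assembly_json
#' @export
read_assembly_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mods <- x$modules
  modules <- lapply(seq_len(nrow(mods)), function(i) {
    r <- mods[i, ]
    doms <- strsplit(r$domains, "-", fixed = TRUE)[[1]]
    at_call <- if (r$at_specificity == "unknown" && !r$at_discordant) NULL
               else {
      ac <- .new_at_call(r$at_specificity)
      ac$discordant <- isTRUE(r$at_discordant)
      ac
    }
    kr_call <- if (r$kr_type == "absent") NULL
               else structure(list(stereo_type = r$kr_type,
                                   signature = r$kr_signature,
                                   predicted_oh_config = switch(r$kr_type,
                                     A = "S", B = "R", "unknown"),
                                   conflict = FALSE, reason = ""),
                              class = "kr_call")
    structure(list(index = r$index,
                   domains = data.frame(protein_id = r$source_orf,
                                        domain_type = doms,
                                        start = NA_integer_,
                                        end = NA_integer_,
                                        score = NA_real_,
                                        active = TRUE, reason = "",
                                        motif_summary = "",
                                        source_orf = r$source_orf),
                   at_call = at_call, kr_call = kr_call,
                   dh_functional = isTRUE(r$dh_functional),
                   er_present = isTRUE(r$er_present),
                   source_orf = r$source_orf),
              class = "module_model")
  })
  structure(list(modules = modules, te_present = isTRUE(x$te_present)),
            class = "assembly_line")
}

#' Write a per-carbon chemotype table
#'
#' Human-readable TSV: one row per backbone carbon with its state
#' (carbonyl C1, beta-carbon states, methyl branches, bond membership).
#'
#' @param ct A `chemotype_table`.
#' @param path Output path.
#' @param config Optional config list echoed as header comments.
#' @return `path`, invisibly.
#' @export
write_chemotype_tsv <- function(ct, path, config = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (length(config))
    writeLines(sprintf("# config: %s",
                       jsonlite::toJSON(config, auto_unbox = TRUE)), con)
  writeLines(sprintf("# carbon_count: %d", ct$carbon_count), con)
  writeLines(sprintf("# starter_unit: %s", ct$starter_unit), con)
  rows <- data.frame(carbon = seq_len(ct$carbon_count),
                     state = "methylene", note = "")
  rows$state[1] <- "carbonyl"
  for (i in seq_len(nrow(ct$states)))
    rows$state[ct$states$carbon[i]] <- ct$states$state[i]
  for (d in ct$double_bonds$delta) {
    rows$note[d] <- paste0(rows$note[d], sprintf("Δ%d(E) ", d))
    rows$state[d + 1L] <- "enoyl_E"
  }
  for (c in ct$methyl_branches)
    rows$note[c] <- paste0(rows$note[c], "methyl branch ")
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
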