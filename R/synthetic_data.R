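# Seeded simulator: generates multi-ORF PKS proteins with known ground
# truth by concatenating the packaged domain scaffolds, writing
# class-determining residues (AT specificity columns, KR LDD/LED/Trp
# signatures, the loading-module KSq Gln), and applying per-residue
# substitution noise that avoids annotated diagnostic sites unless
# explicitly told to corrupt them. Includes the hard-coded fixture
# reproducing the reedsmycin assembly-line organization.

.LINKER <- "GSTASAPL"

#' Specify a synthetic PKS architecture
#'
#' @param modules Data frame with one row per module, columns: `index`
#'   (0 = loading, then contiguous), `orf` (contiguous split points),
#'   `at` (`"malonyl"`/`"methylmalonyl"`), `kr` (`"A"`, `"B"`,
#'   `"unassigned"`, `"absent"`), `kr_signature` (`"LDD"`, `"LED"`,
#'   `"TRP"`, `"none"`), `dh` (logical: functional DH present), `er`
#'   (logical). Optional `at_note` free-text flags.
#' @param te `TRUE` to append a terminal TE to the last ORF.
#' @param noise_rate Per-residue substitution probability in `[0, 0.5)`.
#' @param seed Integer seed owned by the architecture (all generation
#'   randomness derives from it).
#' @return Object of class `architecture_spec`.
#' @export
architecture_spec <- function(modules, te = TRUE, noise_rate = 0,
                              seed = 1L) {
  stopifnot(is.data.frame(modules), nrow(modules) >= 1L)
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop("architecture_spec: noise rate must be in [0, 0.5)")
  if (!identical(modules$index, seq_len(nrow(modules)) - 1L))
    stop("architecture_spec: module indices must be 0..N contiguous")
  if (is.unsorted(match(modules$orf, unique(modules$orf))))
    stop("architecture_spec: ORF split points must partition modules contiguously")
  if (!"at_note" %in% names(modules)) modules$at_note <- ""
  structure(list(modules = modules, te = te, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

#' The Rdm assembly-line fixture
#'
#' Hard-coded architecture transcribed from the reedsmycin PKS
#' organization: 17 modules (1 loading + 16 extension) over four ORFs
#' (rdmG: loading + modules 1-2; rdmH: 3-6; rdmI: 7-12; rdmJ: 13-16 plus
#' the terminal TE). AT specificities: methylmalonyl-CoA for modules
#' 0-2 (the loading AT0 flagged as phylogeny-vs-structure discordant),
#' malonyl-CoA for 3-16. KR stereo-types: B for 1-3 and 12-16 (LDD
#' signature in 1-3 and 12-14, the LED variant in 15-16), A (Trp) for
#' 6-7 and 9-11, unassigned for 4-5 and 8. Functional DH domains in
#' modules 1-3 and 12-16; the single ER in module 1.
#'
#' @param noise_rate,seed Passed through to [architecture_spec()].
#' @return An `architecture_spec`.
#' @export
make_rdm_fixture <- function(noise_rate = 0, seed = 1L) {
  idx <- 0:16
  orf <- c(rep("rdmG", 3), rep("rdmH", 4), rep("rdmI", 6), rep("rdmJ", 4))
  at <- ifelse(idx <= 2, "methylmalonyl", "malonyl")
  kr <- rep("absent", 17)
  kr[idx %in% c(1, 2, 3, 12, 13, 14, 15, 16)] <- "B"
  kr[idx %in% c(6, 7, 9, 10, 11)] <- "A"
  kr[idx %in% c(4, 5, 8)] <- "unassigned"
  sig <- rep("none", 17)
  sig[idx %in% c(1, 2, 3, 12, 13, 14)] <- "LDD"
  sig[idx %in% c(15, 16)] <- "LED"
  sig[kr == "A"] <- "TRP"
  dh <- idx %in% c(1, 2, 3, 12, 13, 14, 15, 16)
  er <- idx == 1
  at_note <- ifelse(idx == 0, "phylogeny_vs_structure_discordant", "")
  architecture_spec(
    data.frame(index = idx, orf = orf, at = at, kr = kr,
               kr_signature = sig, dh = dh, er = er, at_note = at_note),
    te = TRUE, noise_rate = noise_rate, seed = seed)
}

#' The observed RDM A chemotype
#'
#' Per-carbon facts of the elucidated RDM A structure used for
#' reconciliation: a 34-carbon backbone from an acetate starter,
#' S-configured hydroxyls at C-13/15/17/21/23, hydroxyls of undetermined
#' configuration at C-19/25/27/31, six E-configured double bonds
#' (delta 2-10 and delta 28) and methyl branches at C-30 and C-32.
#'
#' @return An `observed_chemotype`.
#' @export
make_observed_rdma <- function() {
  observed_chemotype(
    carbon_count = 34L,
    hydroxyls = data.frame(
      carbon = c(13L, 15L, 17L, 21L, 23L, 19L, 25L, 27L, 31L),
      config = c(rep("S", 5), rep("unknown", 4))),
    double_bonds = data.frame(delta = c(2L, 4L, 6L, 8L, 10L, 28L),
                              geometry = "E"),
    methyl_branches = c(30L, 32L),
    starter_unit = "acetate")
}

#' Build the ground-truth assembly line of an architecture
#'
#' Constructs the `assembly_line` a perfect annotation of the generated
#' proteins would yield, directly from the architecture labels (no
#' sequences involved). Used as simulator ground truth.
#'
#' @param arch An `architecture_spec`.
#' @return An annotated `assembly_line`.
#' @export
architecture_to_assembly <- function(arch) {
  modules <- lapply(seq_len(nrow(arch$modules)), function(i) {
    r <- arch$modules[i, ]
    doms <- if (r$index == 0L) c("KSQ", "AT", "ACP")
            else c("KS", "AT", if (r$dh) "DH", if (r$er) "ER",
                   if (r$kr != "absent") "KR", "ACP")
    at_call <- .new_at_call(r$at, confidence = 1)
    at_call$discordant <- nzchar(r$at_note)
    kr_call <- if (r$kr == "absent") NULL
               else structure(list(stereo_type = r$kr,
                                   signature = r$kr_signature,
                                   predicted_oh_config = switch(r$kr,
                                     A = "S", B = "R", "unknown"),
                                   conflict = FALSE, reason = ""),
                              class = "kr_call")
    structure(list(index = r$index,
                   domains = data.frame(protein_id = r$orf,
                                        domain_type = doms,
                                        start = NA_integer_,
                                        end = NA_integer_,
                                        score = NA_real_, active = TRUE,
                                        reason = "", motif_summary = "",
                                        source_orf = r$orf),
                   at_call = at_call, kr_call = kr_call,
                   dh_functional = isTRUE(r$dh),
                   er_present = isTRUE(r$er), source_orf = r$orf),
              class = "module_model")
  })
  structure(list(modules = modules, te_present = isTRUE(arch$te)),
            class = "assembly_line")
}

# one domain instance: scaffold + class-determining residue edits;
# returns the sequence and its protected (diagnostic) 1-based positions
.instantiate_domain <- function(type, modrow, reference, panel) {
  sites <- reference$sites
  seq <- reference$scaffolds[[type]]
  plant <- function(seq, start0, txt) {
    substr(seq, start0 + 1L, start0 + nchar(txt)) <- txt
    seq
  }
  if (type == "AT") {
    # draw from the class ancestor so phylogenetic placement carries
    # class signal beyond the diagnostic columns
    seq <- unname(panel$ancestors[[modrow$at]])
    diagr <- sites[sites$domain == "AT" & !is.na(sites$expected_malonyl), ]
    col <- if (modrow$at == "malonyl") diagr$expected_malonyl
           else diagr$expected_methylmalonyl
    for (i in seq_len(nrow(diagr))) seq <- plant(seq, diagr$start[i], col[i])
  } else if (type == "KS" && modrow$index == 0L) {
    cys <- .site(sites, "KS", "ks_cys")
    seq <- plant(seq, cys$start, "Q")
  } else if (type == "KR") {
    bwin <- .site(sites, "KR", "kr_b_window")
    asite <- .site(sites, "KR", "kr_a_site")
    if (modrow$kr == "B")
      seq <- plant(seq, bwin$start,
                   if (modrow$kr_signature == "LED") "LED" else "LDD")
    if (modrow$kr == "A") seq <- plant(seq, asite$start, "W")
  }
  prot <- sites[sites$domain == type, , drop = FALSE]
  protected <- unlist(mapply(function(s, l) seq(s + 1L, s + l),
                             prot$start, prot$length, SIMPLIFY = FALSE))
  list(seq = seq, protected = as.integer(protected))
}

#' Generate synthetic PKS proteins with known ground truth
#'
#' Concatenates domain scaffolds per module (KS-AT-\[DH-\[ER-\]\]\[KR-\]ACP,
#' loading KSq-AT-ACP, terminal TE) with short linkers, injects the
#' class-determining residues, and applies seeded substitution noise
#' that avoids annotated diagnostic sites (unless `corrupt_diagnostics`
#' names them). Identical seeds give byte-identical output.
#'
#' @param arch An `architecture_spec`.
#' @param corrupt_diagnostics Optional data frame with columns
#'   `module` (index) and `site` (a site name from the reference TSV,
#'   e.g. `"acp_ser"`): those residues are substituted regardless of
#'   protection.
#' @param reference,panel Packaged reference data.
#' @return List of class `synthetic_truth`: `records` (one
#'   [protein_record] per ORF), `arch`, `truth_line` (the ground-truth
#'   annotated `assembly_line`), `truth_chemotype`
#'   (= `predict_chemotype(truth_line)`), and `domain_map` (data frame
#'   of planted domains with ORF coordinates).
#' @export
generate_proteins <- function(arch, corrupt_diagnostics = NULL,
                              reference = pks_reference(),
                              panel = pks_at_panel()) {
  stopifnot(inherits(arch, "architecture_spec"))
  set.seed(arch$seed)
  orfs <- unique(arch$modules$orf)
  seqs <- stats::setNames(rep("", length(orfs)), orfs)
  protected <- stats::setNames(vector("list", length(orfs)), orfs)
  dmap <- data.frame(orf = character(), module = integer(),
                     domain_type = character(), start = integer(),
                     end = integer())
  corrupt_abs <- stats::setNames(vector("list", length(orfs)), orfs)
  for (i in seq_len(nrow(arch$modules))) {
    r <- arch$modules[i, ]
    types <- if (r$index == 0L) c("KS", "AT", "ACP")
             else c("KS", "AT", if (r$dh) "DH", if (r$er) "ER",
                    if (r$kr != "absent") "KR", "ACP")
    for (type in types) {
      inst <- .instantiate_domain(type, r, reference, panel)
      off <- nchar(seqs[[r$orf]])
      dmap <- rbind(dmap, data.frame(
        orf = r$orf, module = r$index,
        domain_type = if (type == "KS" && r$index == 0L) "KSQ" else type,
        start = off, end = off + nchar(inst$seq)))
      if (!is.null(corrupt_diagnostics)) {
        cd <- corrupt_diagnostics[corrupt_diagnostics$module == r$index, ,
                                  drop = FALSE]
        for (sname in cd$site) {
          srow <- reference$sites[reference$sites$site == sname, ]
          if (nrow(srow) && srow$domain[1] == type)
            corrupt_abs[[r$orf]] <- c(corrupt_abs[[r$orf]],
                                      off + srow$start[1] +
                                        seq_len(srow$length[1]))
        }
      }
      protected[[r$orf]] <- c(protected[[r$orf]], off + inst$protected)
      seqs[[r$orf]] <- paste0(seqs[[r$orf]], inst$seq, .LINKER)
    }
  }
  if (arch$te) {
    last <- orfs[length(orfs)]
    inst <- .instantiate_domain("TE", arch$modules[1, ], reference, panel)
    off <- nchar(seqs[[last]])
    dmap <- rbind(dmap, data.frame(orf = last, module = NA_integer_,
                                   domain_type = "TE", start = off,
                                   end = off + nchar(inst$seq)))
    protected[[last]] <- c(protected[[last]], off + inst$protected)
    seqs[[last]] <- paste0(seqs[[last]], inst$seq)
  }
  # seeded substitution noise away from protected sites
  for (orf in orfs) {
    ch <- strsplit(seqs[[orf]], "")[[1]]
    free <- setdiff(seq_along(ch), protected[[orf]])
    if (arch$noise_rate > 0 && length(free)) {
      hit <- free[stats::runif(length(free)) < arch$noise_rate]
      ch[hit] <- vapply(ch[hit], function(old)
        sample(setdiff(AA_ALPHABET, old), 1L), character(1))
    }
    for (p in corrupt_abs[[orf]])
      ch[p] <- sample(setdiff(AA_ALPHABET, c(ch[p], "S", "W")), 1L)
    seqs[[orf]] <- paste(ch, collapse = "")
  }
  records <- lapply(orfs, function(o)
    protein_record(o, seqs[[o]], source = "synthetic"))
  truth_line <- architecture_to_assembly(arch)
  structure(list(records = records, arch = arch,
                 truth_line = truth_line,
                 truth_chemotype = predict_chemotype(truth_line),
                 domain_map = dmap),
            class = "synthetic_truth")
}

#' Write a synthetic cluster as a GenBank flat file
#'
#' Minimal single-LOCUS GenBank record with one translated CDS per ORF
#' (back-translated coordinates are placeholders; the translations carry
#' the information). Readable by [read_genbank_cds()].
#'
#' @param truth A `synthetic_truth` from [generate_proteins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(truth, path) {
  recs <- truth$records
  nt_len <- sum(vapply(recs, function(r) 3L * nchar(r$sequence) + 3L,
                       integer(1))) + 200L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       SYNCLUSTER%12d bp    DNA     linear   SYN",
                     nt_len), con)
  writeLines("DEFINITION  synthetic PKS cluster (simulator output).", con)
  writeLines("FEATURES             Location/Qualifiers", con)
  pos <- 101L
  for (r in recs) {
    len <- 3L * nchar(r$sequence) + 3L
    writeLines(sprintf("     CDS             %d..%d", pos, pos + len - 1L),
               con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", r$id), con)
    tr <- r$sequence
    chunks <- substring(tr, seq(1, nchar(tr), 50), pmin(seq(50, nchar(tr) + 49, 50), nchar(tr)))
    writeLines(sprintf("                     /translation=\"%s\"",
                       paste(chunks, collapse = "\n                     ")),
               con)
    pos <- pos + len
  }
  writeLines("//", con)
  invisible(path)
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %d modules over %d ORFs, TE %s, noise %.2f, seed %d\n",
              nrow(x$modules), length(unique(x$modules$orf)),
              if (x$te) "yes" else "no", x$noise_rate, x$seed))
  invisible(x)
}
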