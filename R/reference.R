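# Packaged reference data: synthetic consensus-like domain scaffolds with
# annotated diagnostic sites, and the AT specificity panel (class
# ancestors + leaves). All sequences are synthetic, authored for this
# package; diagnostic positions are 0-based offsets into the scaffold and
# live in editable sidecar TSVs so the residue conventions can be
# swapped out without touching code.

#' Packaged domain scaffolds and diagnostic sites
#'
#' Loads the synthetic domain exemplars (one per domain type) and their
#' annotated catalytic/diagnostic sites.
#'
#' @return List with `scaffolds` (named character vector of exemplar
#'   sequences: KS, AT, DH, ER, KR, ACP, TE) and `sites` (data frame:
#'   `domain`, `site`, `start` 0-based, `length`, expected residues per
#'   AT specificity class, `note`).
#' @export
pks_reference <- function() {
  if (is.null(.pk_env$reference)) {
    fa <- read_fasta(system.file("extdata", "domain_scaffolds.fasta",
                                 package = "pksline", mustWork = TRUE))
    scaffolds <- vapply(fa, function(r) r$sequence, character(1))
    names(scaffolds) <- vapply(fa, function(r) r$id, character(1))
    sites <- utils::read.delim(
      system.file("extdata", "domain_sites.tsv", package = "pksline",
                  mustWork = TRUE),
      stringsAsFactors = FALSE)
    .pk_env$reference <- list(scaffolds = scaffolds, sites = sites)
  }
  .pk_env$reference
}

#' Packaged AT specificity reference panel
#'
#' AT domains of known extender-unit specificity used for residue
#' comparison and phylogenetic placement, plus the two synthetic class
#' ancestors the simulator draws module ATs from.
#'
#' @return List with `records` (list of [protein_record]), `classes`
#'   (named character vector id -> specificity) and `ancestors` (named
#'   character vector of class ancestor sequences).
#' @export
pks_at_panel <- function() {
  if (is.null(.pk_env$at_panel)) {
    recs <- read_fasta(system.file("extdata", "at_panel.fasta",
                                   package = "pksline", mustWork = TRUE))
    meta <- utils::read.delim(
      system.file("extdata", "at_panel.tsv", package = "pksline",
                  mustWork = TRUE), stringsAsFactors = FALSE)
    classes <- stats::setNames(meta$specificity, meta$id)
    anc <- read_fasta(system.file("extdata", "at_class_ancestors.fasta",
                                  package = "pksline", mustWork = TRUE))
    ancestors <- vapply(anc, function(r) r$sequence, character(1))
    names(ancestors) <- vapply(anc, function(r) r$id, character(1))
    .pk_env$at_panel <- list(records = recs, classes = classes,
                             ancestors = ancestors)
  }
  .pk_env$at_panel
}

# site lookup helper: 0-based start of a named site within a scaffold
.site <- function(sites, domain, site) {
  row <- sites[sites$domain == domain & sites$site == site, ]
  if (!nrow(row)) stop("reference site not found: ", domain, "/", site)
  row[1, ]
}
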