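test_that("the Rdm fixture yields 17 modules with a terminal TE", {
  truth <- generate_proteins(make_rdm_fixture())
  hits <- lapply(truth$records, detect_domains)
  names(hits) <- vapply(truth$records, function(r) r$id, "")
  line <- build_assembly_line(hits)
  expect_length(line$modules, 17)
  expect_true(line$te_present)
  expect_equal(vapply(line$modules, function(m) m$index, 1L), 0:16)
  expect_equal(line$modules[[1]]$domains$domain_type[1], "KSQ")
  expect_length(attr(line, "grammar_violations"), 0)
  # index contiguous across ORFs in ORF order
  orfs <- vapply(line$modules, function(m) m$source_orf, "")
  expect_equal(unique(orfs), c("rdmG", "rdmH", "rdmI", "rdmJ"))
})

mk_hits <- function(types) {
  data.frame(protein_id = "orf", domain_type = types,
             start = seq_along(types) * 100L,
             end = seq_along(types) * 100L + 80L,
             score = 100, active = TRUE, reason = "", motif_summary = "")
}

test_that("modules are cut at each KS and orphans attach to loading", {
  line <- build_assembly_line(list(
    orf = mk_hits(c("KSQ", "AT", "ACP", "KS", "AT", "ACP"))))
  expect_length(line$modules, 2)

  orphan <- build_assembly_line(list(
    orf = mk_hits(c("AT", "KSQ", "AT", "ACP", "KS", "AT", "ACP"))))
  expect_length(orphan$modules, 2)
  expect_equal(orphan$modules[[1]]$domains$domain_type,
               c("AT", "KSQ", "AT", "ACP"))
  expect_match(attr(orphan, "grammar_violations")[1], "orphan")

  expect_error(build_assembly_line(list(orf = mk_hits(c("AT", "ACP")))),
               "no modules detectable")
})

test_that("chemotype prediction reproduces the fixture positions", {
  line <- architecture_to_assembly(make_rdm_fixture())
  ct <- predict_chemotype(line)
  expect_equal(ct$carbon_count, 34)
  expect_equal(ct$starter_unit, "propionate")  # raw: AT0 methylmalonyl
  oh <- function(state) sort(ct$states$carbon[ct$states$state == state])
  expect_equal(oh("OH_S"), c(13, 15, 17, 21, 23))
  expect_equal(oh("OH_unknown"), c(19, 25, 27))
  # module 11 KR puts its hydroxyl at C13, module 6 at C23
  expect_equal(ct$states$module[ct$states$carbon == 13], 11)
  expect_equal(ct$states$module[ct$states$carbon == 23], 6)
  # raw prediction draws delta 30 too (module 2 DH not yet skipped)
  expect_equal(ct$double_bonds$delta, c(2, 4, 6, 8, 10, 28, 30))
  expect_equal(ct$methyl_branches, c(30, 32))
  # module 1: DH + ER -> methylene at C33, no bond
  expect_equal(ct$states$state[ct$states$carbon == 33], "methylene")
})

test_that("the minimal line gives 4 carbons with a keto at C3", {
  arch <- architecture_spec(data.frame(
    index = 0:1, orf = "o", at = "malonyl", kr = "absent",
    kr_signature = "none", dh = FALSE, er = FALSE),
    te = TRUE, noise_rate = 0, seed = 1)
  ct <- predict_chemotype(architecture_to_assembly(arch))
  expect_equal(ct$carbon_count, 4)
  expect_equal(ct$states$state[ct$states$carbon == 3], "keto")
  expect_equal(ct$starter_unit, "acetate")
})

test_that("closed-form carbon positions equal the chain-growth oracle", {
  for (N in 1:20) {
    line <- architecture_to_assembly(random_architecture(N, seed = 100 + N))
    ct <- predict_chemotype(line)
    want <- oracle_chemotype(line)
    expect_equal(ct$carbon_count, want$carbon_count)
    got_states <- ct$states[order(ct$states$carbon),
                            c("carbon", "state")]
    rownames(got_states) <- rownames(want$states) <- NULL
    expect_equal(got_states, want$states, info = paste("N =", N))
    expect_equal(ct$double_bonds$delta, want$double_bonds)
    expect_equal(ct$methyl_branches, want$methyl_branches)
    expect_equal(ct$starter_unit, want$starter_unit)
  }
})

test_that("chemotype invariants hold across random architectures", {
  for (seed in 1:15) {
    N <- 3 + (seed %% 10)
    line <- architecture_to_assembly(random_architecture(N, seed = seed))
    ct <- predict_chemotype(line)
    expect_equal(ct$carbon_count %% 2, 0)
    oh <- ct$states$carbon[grepl("^OH", ct$states$state)]
    expect_true(all(oh %% 2 == 1))                 # hydroxyls odd
    expect_true(all(ct$methyl_branches %% 2 == 0)) # methyls even
    expect_true(all(oh <= 2 * N + 1))
    # bond count = B-type KRs with functional DH and no ER
    mods <- line$modules[-1]
    nb <- sum(vapply(mods, function(m)
      !is.null(m$kr_call) && m$kr_call$stereo_type == "B" &&
        m$dh_functional && !m$er_present, logical(1)))
    expect_equal(nrow(ct$double_bonds), nb)
  }
})

test_that("reconciliation of the raw fixture against RDM A finds exactly
           the starter and the module-2 DH skip", {
  line <- architecture_to_assembly(make_rdm_fixture())
  ct <- predict_chemotype(line)
  disc <- reconcile(ct, make_observed_rdma())
  expect_equal(nrow(disc), 2)
  expect_setequal(disc$category, c("at_specificity", "dh_skip"))
  expect_equal(disc$module_index[disc$category == "at_specificity"], 0)
  expect_equal(disc$module_index[disc$category == "dh_skip"], 2)

  # applying the overrides regenerates a fully consistent chemotype
  line2 <- apply_reconciliation(line, disc)
  ct2 <- predict_chemotype(line2)
  expect_equal(nrow(reconcile(ct2, make_observed_rdma())), 0)
  expect_equal(ct2$double_bonds$delta, c(2, 4, 6, 8, 10, 28))
  expect_equal(ct2$starter_unit, "acetate")
})

test_that("reconcile is empty on self-encoding and counts perturbations", {
  line <- architecture_to_assembly(make_rdm_fixture())
  ct <- predict_chemotype(line)
  obs0 <- chemotype_as_observed(ct)
  expect_equal(nrow(reconcile(ct, obs0)), 0)

  # k independent perturbations -> exactly k discrepancies
  set.seed(55)
  for (k in 1:4) {
    obs <- obs0
    known <- which(obs$hydroxyls$config %in% c("R", "S"))
    flip <- sample(known, min(k, length(known)))
    obs$hydroxyls$config[flip] <-
      ifelse(obs$hydroxyls$config[flip] == "S", "R", "S")
    extra <- k - length(flip)
    if (extra > 0) {  # add methyls at untouched even carbons
      free <- setdiff(seq(2, obs$carbon_count, 2),
                      c(obs$methyl_branches, obs$double_bonds$delta,
                        obs$double_bonds$delta + 1))
      obs$methyl_branches <- sort(c(obs$methyl_branches,
                                    head(free, extra)))
    }
    expect_equal(nrow(reconcile(ct, obs)), k, info = paste("k =", k))
  }

  # size mismatch short-circuits into one fatal discrepancy
  small <- observed_chemotype(10, starter_unit = "acetate")
  disc <- reconcile(ct, small)
  expect_equal(nrow(disc), 1)
  expect_equal(disc$category, "other")
})

test_that("titer fold changes reproduce the printed production ratios", {
  expect_equal(titer_fold_change(10, 10), 1.00)
  expect_equal(titer_fold_change(155.3, 73.8), 2.10)
  expect_equal(titer_fold_change(184.8, 73.8), 2.50)
  expect_equal(titer_fold_change(73.8, 52.5), 1.41)
  expect_error(titer_fold_change(-1, 5), "positive")
  expect_error(titer_fold_change(5, 0), "positive")
})
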