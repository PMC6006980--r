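ref <- pks_reference()
panel <- pks_at_panel()

kr_with <- function(b = NULL, a = NULL) {
  s <- ref$scaffolds[["KR"]]
  if (!is.null(b)) substr(s, 41, 43) <- b      # B window, 0-based 40
  if (!is.null(a)) substr(s, 56, 56) <- a      # A site, 0-based 55
  s
}

test_that("KR stereo-typing follows the signature table", {
  b <- classify_kr(kr_with(b = "LDD"), ref)
  expect_equal(b$stereo_type, "B")
  expect_equal(b$signature, "LDD")
  expect_equal(b$predicted_oh_config, "R")

  led <- classify_kr(kr_with(b = "LED"), ref)
  expect_equal(led$stereo_type, "B")
  expect_equal(led$signature, "LED")

  a <- classify_kr(kr_with(a = "W"), ref)
  expect_equal(a$stereo_type, "A")
  expect_equal(a$signature, "TRP")
  expect_equal(a$predicted_oh_config, "S")

  none <- classify_kr(kr_with(), ref)
  expect_equal(none$stereo_type, "unassigned")
  expect_equal(none$signature, "none")
  expect_equal(none$predicted_oh_config, "unknown")

  both <- classify_kr(kr_with(b = "LDD", a = "W"), ref)
  expect_equal(both$stereo_type, "unassigned")
  expect_true(both$conflict)

  short <- classify_kr("MKLV", ref)
  expect_equal(short$stereo_type, "unassigned")
  expect_equal(short$reason, "region_too_short")
})

test_that("KR calls never pair a configuration with a missing signature", {
  # property over random perturbations of the diagnostic windows
  set.seed(31)
  for (i in 1:30) {
    s <- kr_with(b = paste(sample(AA20, 3, replace = TRUE), collapse = ""),
                 a = sample(AA20, 1))
    call <- classify_kr(s, ref)
    if (call$signature == "none")
      expect_identical(call$predicted_oh_config, "unknown")
    if (call$predicted_oh_config == "R")
      expect_true(call$signature %in% c("LDD", "LED"))
    if (call$predicted_oh_config == "S")
      expect_identical(call$signature, "TRP")
  }
})

at_of_class <- function(class, noise = 0, seed = 1) {
  arch <- architecture_spec(data.frame(
    index = 0:1, orf = "o", at = c("malonyl", class),
    kr = "absent", kr_signature = "none", dh = FALSE, er = FALSE),
    te = FALSE, noise_rate = noise, seed = seed)
  truth <- generate_proteins(arch)
  dm <- truth$domain_map
  row <- dm[dm$module == 1 & dm$domain_type == "AT", ]
  substr(truth$records[[1]]$sequence, row$start + 1, row$end)
}

test_that("residue-based AT calls recover the planted class", {
  mal <- classify_at_residues(at_of_class("malonyl"), ref)
  expect_equal(mal$specificity, "malonyl")
  expect_equal(mal$confidence, 1.0)
  mm <- classify_at_residues(at_of_class("methylmalonyl"), ref)
  expect_equal(mm$specificity, "methylmalonyl")
  expect_equal(mm$confidence, 1.0)
})

test_that("a half-and-half diagnostic chimera is called unknown", {
  diag <- ref$sites[ref$sites$domain == "AT" &
                    !is.na(ref$sites$expected_malonyl), ]
  s <- at_of_class("malonyl")
  for (i in 3:4)  # flip two of four columns to the methylmalonyl residue
    substr(s, diag$start[i] + 1, diag$start[i] + 1) <-
      diag$expected_methylmalonyl[i]
  chim <- classify_at_residues(s, ref)
  expect_equal(chim$specificity, "unknown")
  expect_equal(chim$reason, "tied_vote")
})

test_that("confidence does not increase as diagnostic columns are mutated", {
  diag <- ref$sites[ref$sites$domain == "AT" &
                    !is.na(ref$sites$expected_malonyl), ]
  s0 <- at_of_class("malonyl")
  prev <- classify_at_residues(s0, ref)$confidence
  s <- s0
  for (k in 1:4) {
    substr(s, diag$start[k] + 1, diag$start[k] + 1) <- "V"  # neither class
    conf <- classify_at_residues(s, ref)$confidence
    expect_lte(conf, prev)
    prev <- conf
  }
})

test_that("phylogenetic placement recovers class; identical query gets 100%", {
  q <- panel$records[[1]]$sequence   # identical to a malonyl panel member
  call <- classify_at_phylo(q, panel, n_bootstrap = 30, seed = 4)
  expect_equal(call$specificity, "malonyl")
  expect_equal(call$tree_support, 100)

  mm <- classify_at_phylo(at_of_class("methylmalonyl"), panel)
  expect_equal(mm$specificity, "methylmalonyl")
})

test_that("noise-free residue and phylogeny calls agree with ground truth", {
  for (class in c("malonyl", "methylmalonyl")) {
    region <- at_of_class(class)
    expect_equal(classify_at_residues(region, ref)$specificity, class)
    expect_equal(classify_at_phylo(region, panel)$specificity, class)
  }
})

test_that("discordant evidence is retained and precedence is configurable", {
  # malonyl diagnostic residues grafted onto a methylmalonyl panel leaf:
  # residues say malonyl, the tree says methylmalonyl
  diag <- ref$sites[ref$sites$domain == "AT" &
                    !is.na(ref$sites$expected_malonyl), ]
  s <- Filter(function(r) r$id == "met_1", panel$records)[[1]]$sequence
  for (i in seq_len(nrow(diag)))
    substr(s, diag$start[i] + 1, diag$start[i] + 1) <-
      diag$expected_malonyl[i]
  call <- classify_at(s, ref, panel, use_phylo = TRUE)
  expect_true(call$discordant)
  expect_equal(call$specificity, "malonyl")        # residue precedence
  expect_equal(call$phylo_call$specificity, "methylmalonyl")
  call2 <- classify_at(s, ref, panel, use_phylo = TRUE,
                       precedence = "phylogeny")
  expect_equal(call2$specificity, "methylmalonyl")
})

test_that("DH/ER functionality reads the module's hits", {
  doms <- data.frame(domain_type = c("KS", "AT", "DH", "ER", "KR", "ACP"),
                     active = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  fn <- call_dh_er_functionality(doms)
  expect_true(fn$dh_functional); expect_true(fn$er_present)
  doms$active[doms$domain_type == "DH"] <- FALSE  # motif destroyed
  fn <- call_dh_er_functionality(doms)
  expect_false(fn$dh_functional)
  fn <- call_dh_er_functionality(doms[doms$domain_type != "ER", ])
  expect_false(fn$er_present)
})

test_that("fixture module 1 is DH-functional with an ER", {
  truth <- generate_proteins(make_rdm_fixture())
  hits <- detect_domains(truth$records[[1]])  # rdmG
  line <- build_assembly_line(list(rdmG = hits))
  fn <- call_dh_er_functionality(line$modules[[2]]$domains)
  expect_true(fn$dh_functional)
  expect_true(fn$er_present)
})
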