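# Independent oracles used to freeze expected values. Each is a
# deliberately naive re-derivation kept separate from the package code
# paths it checks.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# ---- brute-force motif scanner -----------------------------------------
# Expands "(x)" optionals into concrete strings, then checks every start
# offset position by position.
oracle_scan <- function(sequence, pattern, max_mismatch) {
  expand <- function(p) {
    i <- regexpr("(x)", p, fixed = TRUE)
    if (i < 0) return(p)
    with_x <- sub("(x)", "x", p, fixed = TRUE)
    without <- sub("(x)", "", p, fixed = TRUE)
    c(expand(with_x), expand(without))
  }
  hits <- data.frame(position = integer(), mismatches = integer(),
                     length = integer())
  seq_chars <- strsplit(sequence, "")[[1]]
  for (variant in unique(expand(pattern))) {
    # tokenize: "A/B" one position, "x" wildcard, letters fixed
    toks <- list(); ch <- strsplit(variant, "")[[1]]; i <- 1
    while (i <= length(ch)) {
      if (ch[i] == "x") { toks[[length(toks) + 1]] <- "x"; i <- i + 1 }
      else {
        allowed <- ch[i]; i <- i + 1
        while (i + 1 <= length(ch) && ch[i] == "/") {
          allowed <- c(allowed, ch[i + 1]); i <- i + 2
        }
        toks[[length(toks) + 1]] <- allowed
      }
    }
    L <- length(toks)
    if (L > length(seq_chars)) next
    for (s in 0:(length(seq_chars) - L)) {
      mm <- 0
      for (k in seq_len(L)) {
        t <- toks[[k]]
        if (identical(t, "x")) next
        if (!(seq_chars[s + k] %in% t)) mm <- mm + 1
      }
      if (mm <= max_mismatch)
        hits <- rbind(hits, data.frame(position = s, mismatches = mm,
                                       length = L))
    }
  }
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$position, hits$mismatches, -hits$length), ]
  hits <- hits[!duplicated(hits$position), ]
  rownames(hits) <- NULL
  hits
}

# ---- textbook global alignment DP (score only) -------------------------
# Same scoring convention as the package (gap of length k costs
# open + k * ext) but written as the plain three-matrix recurrence.
oracle_nw_score <- function(a, b, S, open = 10, ext = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc); NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- S[ac[i - 1], bc[j - 1]] +
      max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# ---- unit-by-unit chain-growth chemotype oracle ------------------------
# Grows the chain one condensation at a time (module 1 first), applying
# each module's reductive loop to the beta carbon (the previous chain's
# thioester carbonyl), then reads positions off the final chain, whose
# head IS carbon 1. Entirely independent of the closed-form position
# formulas.
oracle_chemotype <- function(line) {
  mods <- line$modules
  N <- length(mods) - 1
  kr_state <- function(mod) {
    if (is.null(mod$kr_call)) return("keto")
    switch(mod$kr_call$stereo_type, A = "OH_S", B = "OH_R",
           unassigned = "OH_unknown", "keto")
  }
  at_of <- function(mod)
    if (is.null(mod$at_call)) "unknown" else mod$at_call$specificity
  # chain: list of carbons head-first (head = thioester carbonyl)
  chain <- list(list(state = "thio", methyl = FALSE),
                list(state = "end", methyl = FALSE))
  starter <- if (at_of(mods[[1]]) == "methylmalonyl") "propionate"
             else "acetate"
  for (m in seq_len(N)) {
    mod <- mods[[m + 1]]
    beta <- chain[[1]]           # old thioester carbonyl becomes beta
    st <- kr_state(mod)
    bond <- FALSE
    if (mod$dh_functional && !is.null(mod$kr_call)) {
      if (st == "OH_R") {
        if (mod$er_present) st <- "methylene" else { st <- "enoyl_E"; bond <- TRUE }
      }
    }
    beta$state <- st
    alpha <- list(state = "alpha", methyl = at_of(mod) == "methylmalonyl",
                  bond_to_next = bond)
    newc <- list(state = "thio", methyl = FALSE)
    chain <- c(list(newc, alpha, beta), chain[-1])
  }
  states <- data.frame(carbon = integer(), state = character())
  bonds <- integer(); methyls <- integer()
  for (k in seq_along(chain)) {
    c_ <- chain[[k]]
    if (c_$state %in% c("keto", "OH_R", "OH_S", "OH_unknown",
                        "enoyl_E", "methylene"))
      states <- rbind(states, data.frame(carbon = k, state = c_$state))
    if (isTRUE(c_$methyl)) methyls <- c(methyls, k)
    if (isTRUE(c_$bond_to_next)) bonds <- c(bonds, k)
  }
  list(carbon_count = length(chain), states = states,
       double_bonds = sort(bonds), methyl_branches = sort(methyls),
       starter_unit = starter)
}

# random architecture with N extension modules (loading + N), seeded
random_architecture <- function(N, seed) {
  set.seed(seed)
  idx <- 0:N
  kr <- c("absent", sample(c("A", "B", "unassigned", "absent"), N,
                           replace = TRUE))
  sig <- ifelse(kr == "A", "TRP", ifelse(kr == "B", "LDD", "none"))
  dh <- c(FALSE, kr[-1] == "B" & stats::runif(N) < 0.6)
  er <- c(FALSE, dh[-1] & stats::runif(N) < 0.3)
  architecture_spec(data.frame(
    index = idx,
    orf = rep("orf1", N + 1),
    at = sample(c("malonyl", "methylmalonyl"), N + 1, replace = TRUE),
    kr = kr, kr_signature = sig, dh = dh, er = er),
    te = TRUE, noise_rate = 0, seed = seed)
}

# distances on a tree = additive matrix; topology comparison helper
unrooted_rf <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
}
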