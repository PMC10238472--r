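sig_of <- function(entities, signs, mags = NULL)
  signed_signature(entities, signs, magnitude = mags)

test_that("signature construction keeps signs, magnitudes, and the top subset", {
  dr <- data.frame(protein = c("P1", "P2", "P3"),
                   log2fc = c(-0.2, 0.1, 0),
                   p = c(0.01, 0.2, 0.9))
  dr$p_adj <- p.adjust(dr$p, "BH")
  expect_warning(full <- build_signature(dr, "full"), "zero")
  expect_equal(full$entity, c("P1", "P2"))
  expect_equal(full$sign, c(-1, 1))
  expect_equal(full$magnitude, c(-0.2, 0.1))
  top <- suppressWarnings(build_signature(dr, "top", alpha = 0.05))
  expect_equal(top$entity, "P1")
})

test_that("a synthetic result with 240 nominal proteins yields a top signature of 240", {
  set.seed(7)
  n <- 1613
  p <- c(runif(240, 0, 0.049), runif(n - 240, 0.051, 1))
  dr <- data.frame(protein = paste0("P", 1:n),
                   log2fc = -abs(rnorm(n, 0.2, 0.05)), p = p,
                   p_adj = p.adjust(p, "BH"))
  expect_equal(nrow(build_signature(dr, "top", alpha = 0.05)), 240)
  expect_equal(nrow(build_signature(dr, "full")), 1613)
})

test_that("knockdown correlation recovers exact flips and skips degenerate genes", {
  ent <- paste0("P", 1:20)
  mag <- seq(-1, 1, length.out = 20)
  sig <- sig_of(ent, sign(mag + 1e-9), mag)
  atlas <- rbind(
    data.frame(gene = "flip", entity = ent, value = -mag),
    data.frame(gene = "same", entity = ent, value = mag),
    data.frame(gene = "const", entity = ent, value = 1),
    data.frame(gene = "tiny", entity = ent[1:3], value = mag[1:3]))
  res <- correlate_knockdown(atlas, sig, min_shared = 10)
  expect_equal(res$rho[res$gene == "flip"], -1)
  expect_equal(res$rho[res$gene == "same"], 1)
  expect_equal(res$status[res$gene == "const"], "constant vector")
  expect_equal(res$status[res$gene == "tiny"], "too few shared entities")
})

test_that("independent random knockdown signatures are uncorrelated on average", {
  ent <- paste0("P", 1:30)
  sig <- sig_of(ent, rep(c(1, -1), 15), seq(-1.5, 1.5, length.out = 30))
  rhos <- vapply(1:200, function(s) {
    set.seed(2000 + s)
    atlas <- data.frame(gene = "g", entity = ent, value = rnorm(30))
    correlate_knockdown(atlas, sig)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)) + 1e-8)
})

test_that("nomination follows the drug-target action alignment rules", {
  corr <- data.frame(gene = c("G1", "G2", "G3"),
                     n_shared = 50, rho = c(-0.4, 0.4, -0.01),
                     p = c(1e-4, 1e-4, 0.9),
                     sign = c(-1, 1, -1), status = "ok")
  drugs <- data.frame(drug = c("a", "b", "c", "d", "e"),
                      gene = c("G1", "G1", "G2", "G2", "G3"),
                      action = c("antagonist", "potentiator", "potentiator",
                                 "inhibitor", "antagonist"))
  cand <- nominate_drugs(corr, drugs, alpha = 0.01)
  # negative correlation + antagonist: in; + potentiator: out
  expect_true("a" %in% cand$drug)
  expect_false("b" %in% cand$drug)
  # positive correlation + potentiator: in; + inhibitor: out
  expect_true("c" %in% cand$drug)
  expect_false("d" %in% cand$drug)
  # non-significant correlation never nominated
  expect_false("e" %in% cand$drug)
  # unknown actions are skipped with a warning
  drugs2 <- rbind(drugs, data.frame(drug = "f", gene = "G1",
                                    action = "mystery"))
  expect_warning(nominate_drugs(corr, drugs2, alpha = 0.01), "mystery")
  # free-text action synonyms are normalized
  drugs3 <- data.frame(drug = "g", gene = "G1", action = "Blocker")
  expect_equal(nominate_drugs(corr, drugs3, alpha = 0.01)$action,
               "antagonist")
})

test_that("the subset-consistency filter drops sign-flipping genes", {
  ent <- paste0("P", 1:60)
  mag <- c(seq(-2, -1, length.out = 15), seq(0.1, 2, length.out = 45))
  full <- sig_of(ent, sign(mag), mag)
  top <- sig_of(ent[1:15], sign(mag[1:15]), mag[1:15])
  # gene concordant off the top subset, discordant on it
  incon <- ifelse(ent %in% top$entity, -mag, mag)
  atlas <- rbind(data.frame(gene = "incon", entity = ent, value = incon),
                 data.frame(gene = "good", entity = ent, value = -mag),
                 data.frame(gene = "narrow", entity = ent[16:60],
                            value = -mag[16:60]))
  corr <- correlate_knockdown(atlas, full)
  drugs <- data.frame(drug = c("di", "dg", "dn"),
                      gene = c("incon", "good", "narrow"),
                      action = c("potentiator", "antagonist", "antagonist"))
  cand <- nominate_drugs(corr, drugs, alpha = 0.05)
  expect_setequal(cand$drug, c("di", "dg", "dn"))
  filt <- subset_consistency_filter(atlas, full, top, cand, min_shared = 10)
  expect_false("di" %in% filt$drug)             # rho_full > 0, rho_top < 0
  expect_true("dg" %in% filt$drug)              # consistent signs
  # no top-subset overlap: retained but flagged untestable
  expect_true("dn" %in% filt$drug)
  expect_true(filt$untestable[filt$drug == "dn"])
})

test_that("LINCS filtering, averaging and statuses follow the rules", {
  prof <- data.frame(
    drug = rep("d", 4),
    gene = c("g1", "g1", "g2", "g2"),
    z = c(1.5, 0.7, 1.5, 0.2),
    cell_line = "neu", is_cns = TRUE, dose_um = 10)
  s <- lincs_signature(prof, "d")
  expect_equal(s$entity, "g1")                  # mean 1.1 > 1; g2: 0.85 out
  expect_equal(s$sign, 1)
  expect_equal(s$magnitude, 1.1)
  expect_equal(attr(s, "status"), "ok")
  # dose filter
  prof2 <- transform(prof, dose_um = 0.5)
  expect_equal(attr(lincs_signature(prof2, "d"), "status"),
               "no test at qualifying dose")
  # non-CNS only
  prof3 <- transform(prof, is_cns = FALSE)
  expect_equal(attr(lincs_signature(prof3, "d"), "status"),
               "not tested in CNS cells")
  expect_equal(nrow(lincs_signature(prof3, "d")), 0)
  # absent drug
  expect_equal(attr(lincs_signature(prof, "absent"), "status"), "not found")
})

test_that("Signed Jaccard satisfies its exact identities", {
  a <- sig_of(c("g1", "g2", "g3"), c(1, 1, -1))
  expect_equal(signed_jaccard(a, a), 1)
  flipped <- sig_of(a$entity, -a$sign)
  expect_equal(signed_jaccard(a, flipped), -1)
  b <- sig_of(c("g1", "g2", "g4"), c(1, -1, 1))
  expect_equal(signed_jaccard(a, b), 0)         # (1 - 1) / 4
  expect_equal(signed_jaccard(b, a), 0)
  empty <- suppressWarnings(sig_of(character(0), numeric(0)))
  expect_equal(signed_jaccard(empty, empty), 0)
})

test_that("Signed Jaccard is symmetric, bounded, and reduces to plain Jaccard", {
  for (s in 1:200) {
    set.seed(s)
    na <- sample(1:20, 1); nb <- sample(1:20, 1)
    a <- sig_of(sample(paste0("g", 1:30), na),
                sample(c(-1, 1), na, replace = TRUE))
    b <- sig_of(sample(paste0("g", 1:30), nb),
                sample(c(-1, 1), nb, replace = TRUE))
    j <- signed_jaccard(a, b)
    expect_equal(j, signed_jaccard(b, a))
    expect_lte(abs(j), 1)
  }
  # all signs agree on the intersection -> plain Jaccard
  a <- sig_of(paste0("g", 1:10), rep(1, 10))
  b <- sig_of(paste0("g", 6:12), rep(1, 7))
  expect_equal(signed_jaccard(a, b), 5 / 12)
})

test_that("the engineered reversing drug survives the whole screen", {
  set.seed(10)
  ent <- paste0("P", 1:150)
  mag <- -abs(rnorm(150, 0.3, 0.15))
  mag[1:40] <- mag[1:40] - 0.5                  # strongly reduced subset
  full <- sig_of(ent, sign(mag), mag)
  top <- sig_of(ent[1:40], sign(mag[1:40]), mag[1:40])
  fx <- generate_pharmacology_fixtures(full, top_entities = top$entity,
                                       seed = 11)
  res <- screen_drugs(fx$atlas, fx$drugs, fx$lincs, full, top)
  expect_true("drug_reverser" %in% res$drug)
  expect_false("drug_inconsistent" %in% res$drug)
  expect_false("drug_decoy" %in% res$drug)
  jrev <- res$signed_jaccard[res$drug == "drug_reverser"]
  expect_lt(jrev, 0)
  expect_equal(res$lincs_status[res$drug == "drug_recap"],
               "not tested in CNS cells")
  # deterministic ordering: J ascending, ties by drug name
  expect_equal(res$drug, res$drug[order(res$signed_jaccard, res$drug,
                                        na.last = TRUE)])
})
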