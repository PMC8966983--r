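small_rppa <- function(statuses = c("validated", "caution", "validated",
                                    "other", "validated")) {
  n_ab <- length(statuses)
  samples <- c("s1_drug", "s1_veh", "s2_drug", "s2_veh")
  values <- matrix(seq_len(n_ab * 4), n_ab, 4,
                   dimnames = list(paste0("ab", seq_len(n_ab)), samples))
  rppa_matrix(
    values,
    antibody_meta = data.frame(antibody = paste0("ab", seq_len(n_ab)),
                               status = statuses, stringsAsFactors = FALSE),
    sample_meta = data.frame(
      sample = samples, cell_line = c("s1", "s1", "s2", "s2"),
      sensitivity = "sensitive",
      treatment = c("drug", "vehicle", "drug", "vehicle"),
      timepoint = "24h", stringsAsFactors = FALSE
    )
  )
}

test_that("validated-antibody filtering drops caution and other statuses", {
  rppa <- small_rppa()
  expect_message(filtered <- filter_validated(rppa), "2 non-validated")
  expect_equal(rownames(filtered$values), c("ab1", "ab3", "ab5"))
  expect_false(any(filtered$antibody_meta$status != "validated"))

  all_ok <- small_rppa(rep("validated", 4))
  expect_equal(filter_validated(all_ok)$values, all_ok$values)

  none <- small_rppa(rep("caution", 3))
  expect_error(filter_validated(none), "no validated")
})

test_that("moderated t matches the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  spec <- generator_spec(seed = 7,
                         rppa_spec = list(n_antibodies = 300, n_planted = 20))
  gr <- gen_rppa_matrix(spec)
  stratum <- list(timepoint = "72h", sensitivity = "sensitive")
  res <- moderated_t_test(gr$rppa, stratum = stratum)

  meta <- gr$rppa$sample_meta
  keep <- meta$timepoint == "72h" & meta$sensitivity == "sensitive"
  vals <- gr$rppa$values[, meta$sample[keep]]
  design <- stats::model.matrix(~ (meta$treatment[keep] == "drug"))
  lfit <- limma::eBayes(limma::lmFit(vals, design))
  tab <- limma::topTable(lfit, coef = 2, number = Inf, sort.by = "none")

  expect_equal(res$log_fc, unname(tab$logFC), tolerance = 1e-10)
  expect_equal(res$t_mod, unname(tab$t), tolerance = 0.02)
  expect_equal(res$p, unname(tab$P.Value), tolerance = 0.01)
})

test_that("with prior df 0 the moderated t is the ordinary two-sample t", {
  spec <- generator_spec(seed = 2,
                         rppa_spec = list(n_antibodies = 50, n_planted = 5))
  gr <- gen_rppa_matrix(spec)
  stratum <- list(timepoint = "24h", sensitivity = "resistant")
  res <- moderated_t_test(gr$rppa, stratum = stratum, prior_df = 0)

  meta <- gr$rppa$sample_meta
  keep <- meta$timepoint == "24h" & meta$sensitivity == "resistant"
  vals <- gr$rppa$values[, meta$sample[keep]]
  drug <- meta$treatment[keep] == "drug"
  ords <- apply(vals, 1, function(x) {
    o <- student_t_oracle(x[drug], x[!drug])
    c(o$t, o$p)
  })
  expect_equal(res$t_mod, unname(ords[1, ]))
  expect_equal(res$p, unname(ords[2, ]))
})

test_that("identical sample variances are a fixed point of the shrinkage", {
  samples <- paste0("s", 1:6)
  base <- c(-1, 0, 1)
  values <- rbind(ab1 = c(5 + base, 3 + base),
                  ab2 = c(1 + base, 1.5 + base),
                  ab3 = c(-2 + base, 0 + base))
  colnames(values) <- samples
  rppa <- rppa_matrix(
    values,
    antibody_meta = data.frame(antibody = rownames(values), status = "validated"),
    sample_meta = data.frame(
      sample = samples, cell_line = rep(paste0("l", 1:3), 2),
      sensitivity = "sensitive",
      treatment = rep(c("drug", "vehicle"), each = 3), timepoint = "24h"
    )
  )
  res <- moderated_t_test(rppa)
  drug_cols <- 1:3
  ord_t <- vapply(seq_len(3), function(i) {
    student_t_oracle(values[i, 1:3], values[i, 4:6])$t
  }, numeric(1))
  expect_equal(res$t_mod, ord_t)
  expect_equal(res$log_fc, c(2, -0.5, -2))
})

test_that("arms below two samples raise a stratum error", {
  rppa <- small_rppa(rep("validated", 3))
  meta <- rppa$sample_meta
  meta$treatment[2] <- "drug"   # leaves one vehicle sample
  broken <- rppa_matrix(rppa$values, rppa$antibody_meta, meta)
  expect_error(moderated_t_test(broken), ">= 2 samples")
})

test_that("BH adjustment equals the brute-force step-up on random p-vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_force_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in raw p
  }
})

test_that("results are invariant to antibody row order", {
  spec <- generator_spec(seed = 5,
                         rppa_spec = list(n_antibodies = 80, n_planted = 8))
  gr <- gen_rppa_matrix(spec)
  res1 <- moderated_t_test(gr$rppa, stratum = list(timepoint = "72h"))
  perm <- sample(nrow(gr$rppa$values))
  shuffled <- rppa_matrix(gr$rppa$values[perm, ],
                          gr$rppa$antibody_meta[perm, ],
                          gr$rppa$sample_meta)
  res2 <- moderated_t_test(shuffled, stratum = list(timepoint = "72h"))
  res2 <- res2[match(res1$antibody, res2$antibody), ]
  expect_equal(res2$t_mod, res1$t_mod[match(res1$antibody, res1$antibody)])
  expect_equal(res2$fdr, res1$fdr)
})

test_that("set comparison reports shared and stratum-unique antibodies by direction", {
  mk <- function(ab, sig, dir) {
    data.frame(antibody = ab, log_fc = ifelse(dir == "up", 1, -1),
               t_mod = 0, p = 0.5, fdr = 0.5, significant = sig,
               direction = dir, stringsAsFactors = FALSE)
  }
  a <- rbind(mk(c("x", "y"), TRUE, "up"), mk("q", TRUE, "down"),
             mk("z", FALSE, "up"))
  b <- rbind(mk(c("y", "z"), TRUE, "up"), mk("q", TRUE, "down"))
  cmp <- set_comparison(list(early = a, late = b))
  expect_equal(cmp$up$shared, "y")
  expect_equal(cmp$up$unique_early, "x")
  expect_equal(cmp$up$unique_late, "z")
  expect_equal(cmp$down$shared, "q")

  same <- set_comparison(list(a = a, b = a))
  expect_equal(same$up$shared, c("x", "y"))
  expect_equal(same$up$unique_a, character(0))
})

test_that("late-only planted antibodies surface as late-only in the comparison", {
  hits <- vapply(1:10, function(s) {
    spec <- generator_spec(
      seed = s,
      rppa_spec = list(n_antibodies = 400, n_planted = 10,
                       planted_timepoints = "72h")
    )
    gr <- gen_rppa_matrix(spec)
    res24 <- moderated_t_test(gr$rppa, stratum = list(timepoint = "24h"))
    res72 <- moderated_t_test(gr$rppa, stratum = list(timepoint = "72h"))
    cmp <- set_comparison(list(h24 = res24, h72 = res72))
    all(gr$truth$planted %in% cmp$up$unique_h72)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
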