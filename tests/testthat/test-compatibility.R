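geno <- function(id, a1, a2, b1, b2, c1, c2) {
  data.frame(id = id, A_1 = a1, A_2 = a2, B_1 = b1, B_2 = b2,
             C_1 = c1, C_2 = c2, stringsAsFactors = FALSE)
}

test_that("the matching rule is subset-at-retained-genes, donor to recipient", {
  cfg <- compatibility_config()
  donor <- geno("d", "A*01:01:01", "A*01:01:01", "B*07:02:01", "B*07:02:01",
                "C*07:02:01", "C*07:02:01")
  rec_het <- geno("r", "A*01:01:01", "A*02:01:01", "B*07:02:01", "B*08:01:01",
                  "C*07:02:01", "C*07:01:01")
  expect_true(donor_matches(donor, rec_het, cfg))     # subset holds
  expect_true(donor_matches(donor, donor, cfg))       # reflexive
  expect_true(donor_matches(rec_het, rec_het, cfg))   # reflexive for heterozygotes

  # empty retention: universal donor
  cfg0 <- compatibility_config(retained = character(0))
  expect_true(donor_matches(rec_het, donor, cfg0))

  # a foreign HLA-B allele blocks the match; knocking out A and B unblocks it
  rec_bad_b <- geno("r2", "A*01:01:01", "A*02:01:01", "B*44:02:01", "B*08:01:01",
                    "C*07:02:01", "C*07:01:01")
  expect_false(donor_matches(donor, rec_bad_b, cfg))
  cfg_c <- apply_knockout(cfg, c("A", "B"))
  expect_equal(cfg_c$retained, "C")
  expect_true(donor_matches(donor, rec_bad_b, cfg_c))

  # not symmetric: homozygous donor -> heterozygous recipient matches,
  # the reverse does not
  expect_true(donor_matches(donor, rec_het, cfg))
  expect_false(donor_matches(rec_het, donor, cfg))
})

test_that("knockout arithmetic on the retained set", {
  cfg <- compatibility_config()
  expect_equal(apply_knockout(cfg, character(0))$retained, c("A", "B", "C"))
  expect_equal(apply_knockout(cfg, c("A", "B"))$retained, "C")
  expect_equal(apply_knockout(cfg, c("A", "B", "C"))$retained, character(0))
})

test_that("coverage equals brute force, self-coverage is 1, curve is monotone", {
  reg <- sample_registry(registry_model(test_pool(5), 60, F = 0.2, seed = 41))
  cfg <- compatibility_config()

  self_cov <- cohort_coverage(reg, reg, cfg, seed = 1)
  expect_equal(self_cov$fraction_matched, 1.0)

  donors <- hla_cohort(reg[1:8, ], label = "panel")
  cov <- cohort_coverage(donors, reg, cfg, seed = 2)
  expect_equal(cov$fraction_matched, oracle_coverage(donors, reg, cfg))
  expect_true(all(diff(cov$curve$fraction) >= 0))
  expect_equal(cov$curve$fraction[nrow(cov$curve)], cov$fraction_matched)
  # endpoint is ordering-invariant
  cov2 <- cohort_coverage(donors, reg, cfg, seed = 999)
  expect_equal(cov2$fraction_matched, cov$fraction_matched)

  # a donor matching nobody but itself
  rare <- geno("rare", "A*79:01:01", "A*79:01:01", "B*79:01:01", "B*79:01:01",
               "C*17:01:01", "C*17:01:01")
  mix <- hla_cohort(rbind(as.data.frame(reg), rare))
  cov3 <- cohort_coverage(hla_cohort(rare), mix, cfg)
  expect_equal(cov3$fraction_matched, 1 / nrow(mix))
  # and with self-pairs excluded it matches nobody
  cov4 <- cohort_coverage(hla_cohort(rare), mix, cfg, exclude_self = TRUE)
  expect_equal(cov4$fraction_matched, 0)
})

test_that("shrinking the retained set never loses coverage", {
  reg <- sample_registry(registry_model(test_pool(6), 120, F = 0.1, seed = 55))
  donors <- hla_cohort(reg[1:10, ], label = "panel")
  chain <- list(c("A", "B", "C"), c("A", "B"), "A", character(0))
  fractions <- vapply(chain, function(ret) {
    cohort_coverage(donors, reg, compatibility_config(retained = ret),
                    seed = 3)$fraction_matched
  }, 0)
  expect_true(all(diff(fractions) >= 0))
  expect_equal(fractions[4], 1.0)
  # pairwise donor-level monotonicity on constructed pairs
  cfg_full <- compatibility_config()
  cfg_sub <- compatibility_config(retained = c("B", "C"))
  for (d in 1:5) {
    for (r in 6:10) {
      full <- donor_matches(reg[d, ], reg[r, ], cfg_full)
      sub <- donor_matches(reg[d, ], reg[r, ], cfg_sub)
      if (full) expect_true(sub)
    }
  }
})

test_that("random-subset baseline spans degenerate and enumerable cases", {
  reg <- sample_registry(registry_model(test_pool(4), 12, F = 0.3, seed = 61))
  cfg <- compatibility_config()
  full <- random_subset_baseline(reg, nrow(reg), cfg, n_reps = 3, seed = 1)
  expect_equal(full$fractions, rep(1.0, 3))
  expect_error(random_subset_baseline(reg, 3, cfg, n_reps = 0), "n_reps")
  expect_error(random_subset_baseline(reg, 100, cfg), "exceeds")

  # exhaustive enumeration oracle at subset size 2
  pairs <- utils::combn(nrow(reg), 2)
  exact <- mean(apply(pairs, 2, function(ix) {
    oracle_coverage(hla_cohort(reg[ix, ]), reg, cfg)
  }))
  sim <- random_subset_baseline(reg, 2, cfg, n_reps = 300, seed = 5)
  mc_se <- sim$sd / sqrt(sim$n_reps)
  expect_lt(abs(sim$mean - exact), 4 * mc_se + 1e-9)
})

test_that("triple-homozygote expectation matches the closed form", {
  single <- list(A = c("A*01:01" = 1), B = c("B*07:02" = 1), C = c("C*01:02" = 1))
  res <- expected_triple_homozygotes(single, n = 50, n_reps = 20, seed = 2)
  expect_equal(res$mean, 50)
  expect_equal(res$sd, 0)

  half <- list(A = c("A*01:01" = 0.5, "A*02:01" = 0.5),
               B = c("B*07:02" = 0.5, "B*08:01" = 0.5),
               C = c("C*01:02" = 0.5, "C*02:02" = 0.5))
  res2 <- expected_triple_homozygotes(half, n = 1000, n_reps = 300, seed = 3)
  expect_equal(res2$closed_form, 125)
  mc_se <- res2$sd / sqrt(300)
  expect_lt(abs(res2$mean - 125), 4 * mc_se)
})
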