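test_that("site extraction finds constructed PAM sites with correct geometry", {
  expect_equal(nrow(find_cas9_sites("ATATATATATATATATATATATATATATAT", score = FALSE)), 0L)

  # one plus-strand site: 4 nt pad + 20-nt protospacer + AGG + 3 nt pad
  proto <- "ACTGACTGACTGACTGACTA"
  seqp <- paste0("TTTT", proto, "AGG", "TTT")
  sites <- find_cas9_sites(seqp, score = FALSE)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$protospacer, proto)
  expect_equal(sites$pam, "AGG")
  expect_equal(sites$proto_start, 5L)
  expect_equal(sites$cut_pos, 5L + 16L)  # boundary 3 bp 5' of the PAM
  expect_equal(sites$context30, seqp)

  # the same site seen from the other strand maps back to plus coordinates
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqp)))
  sites_rc <- find_cas9_sites(rc, score = FALSE)
  expect_equal(nrow(sites_rc), 1L)
  expect_equal(sites_rc$strand, "-")
  expect_equal(sites_rc$protospacer, proto)
  expect_equal(sites_rc$context30, seqp)
  # boundary measured from the other end of the 30-mer
  expect_equal(sites_rc$cut_pos, nchar(seqp) - 21L)

  # a site without full context is dropped but counted
  seq_nopad <- paste0(proto, "AGG")
  s2 <- find_cas9_sites(seq_nopad, score = FALSE)
  expect_equal(nrow(s2), 0L)
  expect_equal(attr(s2, "n_dropped_no_context"), 1L)

  expect_error(find_cas9_sites("ACGTNACGT"), "non-ACGT")
})

test_that("site extraction agrees with the brute-force scan and is strand-symmetric", {
  set.seed(71)
  for (i in 1:5) {
    seq <- random_dna(600)
    got <- find_cas9_sites(seq, score = FALSE)
    want <- oracle_find_sites(seq)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$strand, want$strand)
    expect_equal(got$cut_pos, want$cut_pos)
    expect_equal(got$protospacer, want$protospacer)
    expect_equal(got$pam, want$pam)
    expect_equal(got$context30, want$context30)
    # reverse complement has the same number of sites
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    expect_equal(nrow(find_cas9_sites(rc, score = FALSE)), nrow(got))
  }
})

test_that("Rule Set 1 scores are bounded, deterministic and validated", {
  set.seed(72)
  ctx <- vapply(1:10, function(i) random_dna(30), "")
  s <- ruleset1_score(ctx)
  expect_true(all(s > 0 & s < 1))
  expect_equal(ruleset1_score(ctx), s)
  expect_error(ruleset1_score("ACGT"), "30 nt")
  expect_error(ruleset1_score(paste(rep("N", 30), collapse = "")), "non-ACGT")
  # scoring depends on the 30-mer only, not on where the site sits
  seq <- paste0(random_dna(40), "TTTTACTGACTGACTGACTGACTAAGGTTT", random_dna(40))
  sites <- find_cas9_sites(seq)
  one <- sites[sites$protospacer == "ACTGACTGACTGACTGACTA", ]
  expect_equal(one$score, ruleset1_score(one$context30))
})

test_that("Rule Set 1 agrees with the independent feature-sum oracle", {
  set.seed(73)
  ctx <- vapply(1:20, function(i) random_dna(30), "")
  got <- ruleset1_score(ctx)
  want <- vapply(ctx, oracle_ruleset1, 0)
  expect_lt(max(abs(got - unname(want))), 1e-9)
})

test_that("codon coordinates map through exon junctions and tile the CDS", {
  # two-exon toy: codon 2 is split across the junction
  g <- annotated_gene("A*90:01:01",
                      sequence = paste0("ATGA", "TTTTT", "CGGTAA", "CC"),
                      exons = data.frame(start = c(0, 9), end = c(4, 15)),
                      cds_start = 0, cds_length = 9,
                      tm_span = c(1, 1))
  r1 <- protein_to_cds_coordinate(g, 1)
  expect_equal(r1, data.frame(start = 0L, end = 3L))
  r2 <- protein_to_cds_coordinate(g, 2)
  expect_equal(nrow(r2), 2L)
  expect_equal(sum(r2$end - r2$start), 3L)
  expect_equal(r2$start[1], 3L)
  expect_error(protein_to_cds_coordinate(g, 4), "out of range")

  # tiling: codon intervals cover the exonic CDS exactly once
  toy <- toy_gene_builder(n_alleles = 1, seed = 3)[[1]]
  covered <- integer(0)
  for (res in seq_len(toy$protein_length)) {
    iv <- protein_to_cds_coordinate(toy, res)
    covered <- c(covered, unlist(Map(seq, iv$start, iv$end - 1L)))
  }
  expect_equal(length(covered), toy$cds_length)
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("region flags nest and track the cut position", {
  toy <- toy_gene_builder(n_alleles = 1, seed = 9)[[1]]
  sites <- annotate_site_regions(find_cas9_sites(toy), toy)
  expect_true(all(sites$in_gene_body))
  expect_true(all(sites$in_ectodomain <= sites$in_exon))
  expect_true(all(sites$high_activity <= sites$in_ectodomain))

  tm_nt <- superhla:::.tm_first_nt(toy)
  exon2 <- toy$exons[2, ]
  in_exon2 <- sites$cut_pos > exon2$start & sites$cut_pos < exon2$end
  expect_true(any(in_exon2))
  expect_true(all(sites$in_ectodomain[in_exon2]))  # exon 2 is upstream of the TM

  # cuts at or beyond the TM codon are not ectodomain cuts
  beyond <- sites$cut_pos >= tm_nt
  expect_false(any(sites$in_ectodomain[beyond]))

  # intronic cuts carry no downstream flags
  intronic <- !sites$in_exon
  expect_true(any(intronic))
  expect_false(any(sites$in_ectodomain[intronic]))
})

test_that("deduplication across alleles is set union per stage and idempotent", {
  panel <- toy_gene_builder(n_alleles = 3, n_variant_positions = 8, seed = 15)
  sites <- design_guides(panel)
  u <- unique_sites_across_alleles(sites)
  expect_true(u$counts["gene_body"] >= u$counts["exon"])
  expect_true(u$counts["exon"] >= u$counts["ectodomain"])
  expect_true(u$counts["ectodomain"] >= u$counts["high_activity"])

  # set-algebra oracle: per stage, count distinct 23-mers flagged anywhere
  key <- paste0(sites$protospacer, sites$pam)
  expect_equal(unname(u$counts["gene_body"]), length(unique(key[sites$in_gene_body])))
  expect_equal(unname(u$counts["exon"]), length(unique(key[sites$in_exon])))
  expect_equal(unname(u$counts["ectodomain"]),
               length(unique(key[sites$in_ectodomain])))
  expect_equal(unname(u$counts["high_activity"]),
               length(unique(key[sites$high_activity])))

  # idempotence
  u2 <- unique_sites_across_alleles(u$sites)
  expect_equal(u2$counts, u$counts)
  expect_equal(nrow(u2$sites), nrow(u$sites))

  # two identical alleles add nothing
  twin <- c(panel[1], panel[1])
  names(twin) <- c("a", "b")
  twin[[2]]$allele <- "A*91:01:01"
  u_twin <- unique_sites_across_alleles(design_guides(twin))
  u_one <- unique_sites_across_alleles(design_guides(panel[1]))
  expect_equal(u_twin$counts, u_one$counts)

  # disjoint sequences are additive
  gA <- toy_gene_builder(gene = "A", n_alleles = 1, seed = 21)
  gB <- toy_gene_builder(gene = "B", n_alleles = 1, seed = 22)
  sA <- design_guides(gA); sB <- design_guides(gB)
  kA <- paste0(sA$protospacer, sA$pam); kB <- paste0(sB$protospacer, sB$pam)
  if (length(intersect(kA, kB)) == 0L) {
    u_both <- unique_sites_across_alleles(rbind(sA, sB))
    expect_equal(u_both$counts,
                 unique_sites_across_alleles(sA)$counts +
                   unique_sites_across_alleles(sB)$counts)
  }
})

test_that("HLA-C sparing removes verbatim hits on either strand", {
  panel <- toy_gene_builder(gene = "A", n_alleles = 1, seed = 31)
  cand <- design_guides(panel)
  cand <- cand[cand$in_ectodomain, ][1:5, ]
  c_seq <- random_dna(500)
  # absent everywhere: all retained
  kept <- spare_hla_c_filter(cand, c_seq)
  expect_equal(nrow(kept), 5L)
  # plant candidate 1 verbatim, candidate 2 as reverse complement
  mer1 <- paste0(cand$protospacer[1], cand$pam[1])
  mer2 <- paste0(cand$protospacer[2], cand$pam[2])
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mer2)))
  planted <- paste0(c_seq, mer1, "TTTT", rc2)
  kept2 <- spare_hla_c_filter(cand, planted)
  expect_false(mer1 %in% paste0(kept2$protospacer, kept2$pam))
  expect_false(mer2 %in% paste0(kept2$protospacer, kept2$pam))
  expect_equal(nrow(kept2), 3L)

  # substring-scan oracle on a random panel
  c_seqs <- vapply(1:3, function(i) random_dna(400), "")
  all_cand <- design_guides(panel)
  got <- spare_hla_c_filter(all_cand, c_seqs)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcfun <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  surv <- vapply(seq_len(nrow(all_cand)), function(i) {
    mer <- paste0(all_cand$protospacer[i], all_cand$pam[i])
    !any(vapply(c_seqs, function(s) {
      grepl(mer, s, fixed = TRUE) || grepl(rcfun(mer), s, fixed = TRUE)
    }, TRUE))
  }, TRUE)
  expect_equal(paste0(got$protospacer, got$pam),
               paste0(all_cand$protospacer[surv], all_cand$pam[surv]))
})
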