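make_db_df <- function(n, len, seed, genes = NULL) {
  set.seed(seed)
  data.frame(protein_id = sprintf("p%02d", seq_len(n)),
             gene_id = if (is.null(genes)) sprintf("g%02d", seq_len(n))
                       else genes,
             sequence = random_peptides(n, len),
             stringsAsFactors = FALSE)
}

test_that("peptide databases enumerate every length-k window", {
  one <- data.frame(protein_id = "p1", gene_id = "g1",
                    sequence = random_peptides(1, 15))
  expect_identical(length(build_peptide_db(one, 9)$windows), 7L)
  short <- data.frame(protein_id = "p1", gene_id = "g1",
                      sequence = random_peptides(1, 8))
  expect_identical(length(build_peptide_db(short, 9)$windows), 0L)
  df <- make_db_df(10, 100, seed = 11)
  db <- build_peptide_db(df, 9, "human")
  expect_identical(length(db$windows), 10L * 92L)
  # spot-check window identity against naive substring enumeration
  expect_setequal(db$windows[db$protein_id == "p03"],
                  substring(df$sequence[3], 1:92, 9:100))
  expect_error(build_peptide_db(df[0, ], 9), "empty-database")
})

test_that("FASTA round trip preserves ids and gene tokens", {
  pro <- generate_proteome(5, c(30, 40), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(pro, tmp)
  db <- build_peptide_db(tmp, 9, "human")
  expect_setequal(unique(db$protein_id), sprintf("prot%03d", 1:5))
  expect_setequal(unique(db$gene_id), sprintf("gene%03d", 1:5))
})

test_that("search matches the double-loop oracle including full tie sets", {
  df <- make_db_df(15, 60, seed = 12)
  db <- build_peptide_db(df, 9)
  set.seed(13)
  queries <- c(random_peptides(25),
               substr(df$sequence[4], 11, 19))  # one verbatim hit
  for (q in queries) {
    hits <- search_closest(q, db)
    oracle <- naive_search(q, df)
    expect_identical(unique(hits$raw_score), as.integer(oracle$score))
    expect_setequal(hits$subject, unique(oracle$subjects))
    for (i in seq_len(nrow(hits)))
      expect_setequal(
        strsplit(hits$protein_ids[i], ",")[[1]],
        unique(oracle$protein_ids[oracle$subjects == hits$subject[i]]))
  }
})

test_that("verbatim queries hit themselves; duplicated windows are ties", {
  df <- make_db_df(5, 40, seed = 14)
  q <- substr(df$sequence[2], 6, 14)
  df$sequence[5] <- paste0(substr(df$sequence[5], 1, 20), q)  # plant copy
  db <- build_peptide_db(df, 9)
  hits <- search_closest(q, db)
  expect_identical(hits$subject, q)
  expect_equal(hits$sim_all_pct, 100)
  expect_identical(hits$mismatches, 0L)
  expect_setequal(strsplit(hits$protein_ids, ",")[[1]], c("p02", "p05"))
})

test_that("search output is invariant under database permutation", {
  df <- make_db_df(12, 50, seed = 15)
  set.seed(16)
  q <- random_peptides(1)
  db1 <- build_peptide_db(df, 9)
  db2 <- build_peptide_db(df[sample(nrow(df)), ], 9)
  expect_identical(search_closest(q, db1), search_closest(q, db2))
})

test_that("search validates query length and rejects empty databases", {
  db <- build_peptide_db(make_db_df(3, 30, seed = 17), 9)
  expect_error(search_closest("ACDEFGHI", db), "alignment-length")
  empty <- build_peptide_db(make_db_df(1, 15, seed = 17), 20)
  expect_identical(length(empty$windows), 0L)
  expect_error(search_closest(random_peptides(1, 20), empty),
               "empty-database")
})

test_that("gene match status applies the any-tie rule", {
  hits <- data.frame(subject = c("A", "B"),
                     gene_ids = c("g1,g2", "g3"))
  expect_identical(gene_match_status(hits, "g2"), "matching")
  expect_identical(gene_match_status(hits, "g9"), "nonmatching")
  expect_error(gene_match_status(hits[0, ], "g1"), "no-hit")
})

test_that("novelty profiles equal an independently coded naive pipeline", {
  set.seed(18)
  hu <- make_db_df(8, 60, seed = 19)
  ba <- make_db_df(8, 60, seed = 20)
  vi <- make_db_df(8, 60, seed = 21)
  # pairs carved from the human proteins so gene-matching occurs
  pairs <- do.call(rbind, lapply(1:10, function(i) {
    pi <- sample(8, 1)
    pos <- sample(10:50, 1)
    ref <- substr(hu$sequence[pi], pos, pos)
    alt <- sample(setdiff(aa_standard(), ref), 1)
    enumerate_epitope_pairs(hu$sequence[pi], pos, ref, alt, 9,
                            gene = hu$gene_id[pi])[sample(9, 1), ]
  }))
  allele <- "HLA-A*02:01"
  peps <- unique(c(pairs$tumor_peptide, pairs$normal_peptide,
                   build_peptide_db(hu, 9)$windows))
  aff <- data.frame(peptide = peps, allele = allele,
                    affinity_nm = pseudo_affinity(peps, allele))
  prof <- profile_neoepitopes(pairs, build_peptide_db(hu, 9),
                              build_peptide_db(ba, 9),
                              build_peptide_db(vi, 9), aff, allele)
  mask <- anchor_positions(9)
  for (i in seq_len(nrow(prof))) {
    tum <- prof$tumor_peptide[i]; nor <- prof$normal_peptide[i]
    ta <- aff$affinity_nm[aff$peptide == tum]
    na <- aff$affinity_nm[aff$peptide == nor]
    expect_equal(prof$paired_diff_nm[i], na - ta)
    expect_identical(prof$novel_binding[i],
                     ta < 500 && na >= 500 && na / ta >= 5)
    expect_equal(prof$sim_paired_nonanchor[i],
                 naive_percent(tum, nor, mask))
    oh <- naive_search(tum, hu); ob <- naive_search(tum, ba)
    ov <- naive_search(tum, vi)
    expect_identical(prof$human_raw_score[i], as.integer(oh$score))
    expect_setequal(strsplit(prof$human_subject[i], ",")[[1]],
                    unique(oh$subjects))
    expect_identical(prof$human_match_status[i],
                     if (pairs$gene[i] %in% oh$gene_ids) "matching"
                     else "nonmatching")
    hsub <- sort(unique(oh$subjects))[1]
    expect_equal(prof$human_sim_nonanchor[i],
                 naive_percent(tum, hsub, mask))
    bsub <- sort(unique(ob$subjects))[1]
    vsub <- sort(unique(ov$subjects))[1]
    expect_equal(prof$bacterial_sim_all[i], naive_percent(tum, bsub))
    expect_identical(
      prof$bacterial_closer_nonanchor[i],
      naive_percent(tum, bsub, mask) >
        max(naive_percent(tum, nor, mask),
            naive_percent(tum, hsub, mask)))
    expect_identical(
      prof$viral_closer_all[i],
      naive_percent(tum, vsub) >
        max(naive_percent(tum, nor), naive_percent(tum, hsub)))
  }
})

test_that("profiles handle anchor-position mutations and no-hit sources", {
  prot <- random_peptides(1, 30)
  pos <- 10
  ref <- substr(prot, pos, pos)
  alt <- sample(setdiff(aa_standard(), ref), 1)
  pairs <- enumerate_epitope_pairs(prot, pos, ref, alt, 9, gene = "g1")
  anch <- pairs[pairs$window_position %in% c(2, 9), ][1, ]
  aff <- data.frame(peptide = c(anch$tumor_peptide, anch$normal_peptide),
                    allele = "HLA-A*01:01", affinity_nm = c(100, 1000))
  prof <- profile_neoepitope(anch, NULL, NULL, NULL, aff, "HLA-A*01:01")
  # the only difference sits inside the mask
  expect_equal(prof$sim_paired_nonanchor, 100)
  expect_true(prof$sim_paired_all < 100)
  expect_true(is.na(prof$human_subject))
  expect_true(is.na(prof$bacterial_closer_nonanchor))
  expect_true(is.na(prof$human_match_status))
})

test_that("an identical bacterial window beats all human comparators", {
  hu <- make_db_df(5, 40, seed = 22)
  pairs <- local({
    pos <- 15
    ref <- substr(hu$sequence[1], pos, pos)
    alt <- sample(setdiff(aa_standard(), ref), 1)
    enumerate_epitope_pairs(hu$sequence[1], pos, ref, alt, 9,
                            gene = "g01")[5, ]
  })
  # bacterial protein carrying the tumor peptide verbatim; make sure no
  # human window equals the tumor peptide
  ba <- data.frame(protein_id = "bp1", gene_id = "bg1",
                   sequence = paste0("AAAA", pairs$tumor_peptide, "AAAA"))
  stopifnot(!pairs$tumor_peptide %in% build_peptide_db(hu, 9)$windows)
  aff <- data.frame(peptide = c(pairs$tumor_peptide,
                                pairs$normal_peptide),
                    allele = "X", affinity_nm = c(50, 5000))
  prof <- profile_neoepitope(pairs, build_peptide_db(hu, 9),
                             build_peptide_db(ba, 9), NULL, aff, "X")
  expect_equal(prof$bacterial_sim_all, 100)
  expect_true(prof$bacterial_closer_nonanchor)
  expect_true(prof$bacterial_closer_all)
})
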