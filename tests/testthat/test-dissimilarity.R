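test_that("euclidean_dm reproduces hand geometry", {
  d <- dist_euclidean(rbind(c(0, 0), c(3, 4)))
  expect_equal(d[1, 2], 5)
  expect_equal(dist_euclidean(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
  x <- c(4, 1, 7)
  d1 <- dist_euclidean(x)
  expect_equal(unclass(d1), abs(outer(x, x, "-")), ignore_attr = TRUE)
  expect_error(dist_euclidean(c(1, NA)), "finite")
})

test_that("bray-curtis matches its defining ratio and the textbook cases", {
  t0 <- rbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1))
  expect_equal(dist_bray_curtis(t0)[1, 2], 0.5)
  t1 <- rbind(a = c(2, 3, 1), b = c(2, 3, 1))
  expect_equal(dist_bray_curtis(t1)[1, 2], 0)
  t2 <- rbind(a = c(5, 2, 0, 0), b = c(0, 0, 3, 4))
  expect_equal(dist_bray_curtis(t2)[1, 2], 1)
  expect_error(dist_bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("jaccard works on supports only", {
  tab <- rbind(s1 = c(1, 5, 0), s2 = c(0, 2, 9))  # supports {a,b} vs {b,c}
  expect_equal(dist_jaccard(tab)[1, 2], 2 / 3)
  expect_equal(dist_jaccard(rbind(a = c(1, 2), b = c(9, 1)))[1, 2], 0)
  expect_equal(dist_jaccard(rbind(a = c(1, 0), b = c(0, 3)))[1, 2], 1)
  # abundance-invariance: only presence matters
  expect_equal(unclass(dist_jaccard(tab)),
               unclass(dist_jaccard((tab > 0) * 1)))
  expect_error(dist_jaccard(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))),
               "empty")
})

test_that("jsd has its bounds, identities, and hand value", {
  same <- rbind(a = c(2, 6, 2), b = c(1, 3, 1))  # same proportions
  expect_equal(dist_jsd(same)[1, 2], 0, tolerance = 1e-12)
  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(dist_jsd(disjoint)[1, 2], log(2), tolerance = 1e-12)
  # p = (1, 0), q = (1/2, 1/2): term-by-term hand summation
  m <- c(0.75, 0.25)
  hand <- 0.5 * (1 * log(1 / m[1])) +
    0.5 * (0.5 * log(0.5 / m[1]) + 0.5 * log(0.5 / m[2]))
  tab <- rbind(p = c(2, 0), q = c(3, 3))
  expect_equal(dist_jsd(tab)[1, 2], hand, tolerance = 1e-12)
  set.seed(41)
  tab2 <- random_abundance(6, 8)
  j <- dist_jsd(tab2)
  expect_true(all(j <= log(2) + 1e-12))
  # scaling a sample's counts changes nothing
  tab3 <- tab2; tab3[2, ] <- tab3[2, ] * 17
  expect_equal(unclass(dist_jsd(tab3)), unclass(dist_jsd(tab2)),
               tolerance = 1e-12)
  expect_equal(unclass(dist_jsd(tab2, sqrt = TRUE)),
               sqrt(unclass(dist_jsd(tab2))), tolerance = 1e-12)
})

test_that("jsd agrees with the phyloseq implementation", {
  set.seed(42)
  tab <- random_abundance(8, 10)
  ours <- dist_jsd(tab)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(tab, taxa_are_rows = FALSE))
  ref <- as.matrix(phyloseq::distance(ps, method = "jsd"))
  expect_equal(unclass(ours), ref[rownames(ours), colnames(ours)],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("unifrac identities hold on constructed trees", {
  tips <- paste0("t", 1:4)
  tr <- star_tree(tips)
  # identical communities
  same <- rbind(a = c(3, 1, 0, 2), b = c(3, 1, 0, 2))
  colnames(same) <- tips
  for (v in c("unweighted", "weighted", "generalized")) {
    expect_equal(dist_unifrac(same, tr, v)[1, 2], 0, tolerance = 1e-12)
  }
  # disjoint single-taxon communities on a unit star: maximal for all
  disj <- rbind(a = c(5, 0, 0, 0), b = c(0, 7, 0, 0))
  colnames(disj) <- tips
  for (v in c("unweighted", "weighted", "generalized")) {
    expect_equal(dist_unifrac(disj, tr, v)[1, 2], 1, tolerance = 1e-12)
  }
})

test_that("unifrac matches a branch-by-branch hand computation", {
  # cherry tree ((t1:1, t2:2):0.5, (t3:1, t4:3):0.25);
  tr <- ape::read.tree(text = "((t1:1,t2:2):0.5,(t3:1,t4:3):0.25);")
  tab <- rbind(a = c(4, 4, 2, 0), b = c(0, 2, 2, 4))
  colnames(tab) <- paste0("t", 1:4)
  pa <- c(0.4, 0.4, 0.2, 0)      # proportions of a
  pb <- c(0, 0.25, 0.25, 0.5)    # proportions of b
  # edges: (t1:1) (t2:2) cherry12:0.5 (t3:1) (t4:3) cherry34:0.25
  b_len <- c(1, 2, 0.5, 1, 3, 0.25)
  a_mass <- c(pa[1], pa[2], pa[1] + pa[2], pa[3], pa[4], pa[3] + pa[4])
  b_mass <- c(pb[1], pb[2], pb[1] + pb[2], pb[3], pb[4], pb[3] + pb[4])
  w_hand <- sum(b_len * abs(a_mass - b_mass)) / sum(b_len * (a_mass + b_mass))
  expect_equal(dist_unifrac(tab, tr, "weighted")[1, 2], w_hand,
               tolerance = 1e-12)
  u_hand <- sum(b_len * abs((a_mass > 0) - (b_mass > 0))) /
    sum(b_len * ((a_mass > 0) | (b_mass > 0)))
  expect_equal(dist_unifrac(tab, tr, "unweighted")[1, 2], u_hand,
               tolerance = 1e-12)
  alpha <- 0.5
  s <- a_mass + b_mass
  keep <- s > 0
  g_hand <- sum((b_len * s^alpha * abs(a_mass - b_mass) / s)[keep]) /
    sum((b_len * s^alpha)[keep])
  expect_equal(dist_unifrac(tab, tr, "generalized", alpha = 0.5)[1, 2], g_hand,
               tolerance = 1e-12)
})

test_that("unifrac cross-metric identities hold on random tables", {
  set.seed(43)
  for (rep in 1:5) {
    tab <- random_abundance(6, 7)
    tr <- star_tree(colnames(tab))
    expect_equal(unclass(dist_unifrac(tab, tr, "unweighted")),
                 unclass(dist_jaccard(tab)), tolerance = 1e-10)
    tr2 <- random_rooted_tree(7, seed = rep, tip_labels = colnames(tab))
    expect_equal(unclass(dist_unifrac(tab, tr2, "generalized", alpha = 1)),
                 unclass(dist_unifrac(tab, tr2, "weighted")),
                 tolerance = 1e-10)
  }
})

test_that("unifrac agrees with phyloseq on random data", {
  set.seed(44)
  tab <- random_abundance(7, 9)
  tr <- random_rooted_tree(9, seed = 5, tip_labels = colnames(tab))
  ps <- phyloseq::phyloseq(phyloseq::otu_table(tab, taxa_are_rows = FALSE),
                           phyloseq::phy_tree(tr))
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  ours_w <- dist_unifrac(tab, tr, "weighted")
  expect_equal(unclass(ours_w), ref_w[rownames(ours_w), colnames(ours_w)],
               ignore_attr = TRUE, tolerance = 1e-10)
  ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  ours_u <- dist_unifrac(tab, tr, "unweighted")
  expect_equal(unclass(ours_u), ref_u[rownames(ours_u), colnames(ours_u)],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("unifrac validates its tree inputs", {
  tab <- rbind(a = c(1, 2), b = c(2, 1))
  colnames(tab) <- c("t1", "missing_taxon")
  tr <- star_tree(c("t1", "t2"))
  expect_error(dist_unifrac(tab, tr, "weighted"), "missing_taxon")
  tr0 <- star_tree(c("t1", "t2"), branch_length = 0)
  colnames(tab) <- c("t1", "t2")
  expect_error(dist_unifrac(tab, tr0, "weighted"), "zero")
})

test_that("metric outputs are valid distance matrices in their ranges", {
  set.seed(45)
  tab <- random_abundance(8, 12)
  tr <- random_rooted_tree(12, seed = 9, tip_labels = colnames(tab))
  mats <- list(
    bray = dist_bray_curtis(tab),
    jaccard = dist_jaccard(tab),
    uu = dist_unifrac(tab, tr, "unweighted"),
    wu = dist_unifrac(tab, tr, "weighted"),
    gu = dist_unifrac(tab, tr, "generalized")
  )
  for (m in mats) {
    expect_s3_class(m, "dist_matrix")
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
  }
})

test_that("newick parsing validates and round-trips", {
  tr <- parse_newick("((a:1,b:1):0.5,c:2);")
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_true(ape::is.rooted(tr))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- parse_newick(path = path)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE,
                                   tolerance = 1e-12))
  expect_error(parse_newick("(a:1,a:1);"), "duplicate")
  expect_error(parse_newick("((a:1,b:2;"), "parse")
})
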