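test_that("k-mer profiles are canonical and strand-invariant", {
  p <- kmer_profile("ACGT", k = 3, label = "x")
  # ACG and CGT are reverse complements -> one canonical 3-mer
  expect_equal(sort(p$kmers), "ACG")
  expect_equal(p$total_count, 2L)

  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_setequal(kmer_profile(s, 11)$kmers, kmer_profile(rc, 11)$kmers)

  withN <- kmer_profile(paste0("ACGTN", s), 11)
  expect_true(all(!grepl("N", withN$kmers)))
  expect_error(kmer_profile("NNNNNNNNNNNNNN", 11), "no usable")
  expect_error(kmer_profile(s, 10)) # even k
})

test_that("FASTA files round-trip into identical profiles", {
  dir <- withr::local_tempdir()
  set.seed(50)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  f1 <- file.path(dir, "a.fasta"); f2 <- file.path(dir, "b.fasta")
  write_fasta(c(seq1 = s), f1)
  write_fasta(c(other = s), f2)
  expect_setequal(kmer_profile(f1, 13)$kmers, kmer_profile(f2, 13)$kmers)
})

test_that("AAF distance is a premetric with the documented cap", {
  a <- structure(list(label = "a", k = 5,
                      kmers = c("AAAAA", "AAAAC", "AAAAG"),
                      total_count = 3L), class = "kmer_profile")
  b <- structure(list(label = "b", k = 5,
                      kmers = c("AAAAA", "AAAAC", "AAATT", "AAGTT"),
                      total_count = 4L), class = "kmer_profile")
  disj <- structure(list(label = "d", k = 5, kmers = c("CCCCC"),
                         total_count = 1L), class = "kmer_profile")
  expect_equal(aaf_distance(a, a), 0)
  expect_equal(aaf_distance(a, b), aaf_distance(b, a))
  expect_equal(aaf_distance(a, b), -(1 / 5) * log(2 / 3))
  expect_equal(aaf_distance(a, disj), 1.0)
  expect_equal(aaf_distance(a, disj, d_max = 2.5), 2.5)
  bad_k <- a; bad_k$k <- 7
  expect_error(aaf_distance(a, bad_k), "k mismatch")
})

test_that("AAF distance increases monotonically with substitution rate", {
  tree <- ape::read.tree(text = "(t1:0,t2:0);")
  rates <- c(0.005, 0.01, 0.02, 0.04, 0.08, 0.16)
  set.seed(51)
  d <- vapply(rates, function(r) {
    seqs <- evolve_sequences(tree, 30000, rate = r)
    aaf_distance(kmer_profile(seqs[1], 17), kmer_profile(seqs[2], 17))
  }, numeric(1))
  expect_gt(cor(rates, d, method = "spearman"), 0.95)
})

test_that("similarity matrices convert by the max-normalised rule", {
  s <- matrix(c(10, 4, 2,
                4, 10, 6,
                2, 6, 10), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  d <- similarity_to_distance(s)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d["a", "b"], 1 - 4 / 10)
  expect_equal(d["a", "c"], 1 - 2 / 10)
  # identity-like similarity -> all off-diagonal distances 1
  ident <- diag(3) * 7
  dimnames(ident) <- dimnames(s)
  expect_true(all(similarity_to_distance(ident)[upper.tri(ident)] == 1))
  const <- matrix(10, 3, 3, dimnames = dimnames(s))
  expect_true(all(similarity_to_distance(const) == 0))
  asym <- s; asym[1, 2] <- 9
  expect_error(similarity_to_distance(asym), "asymmetric")
})

test_that("NJ exactly recovers random additive 6-taxon trees", {
  set.seed(52)
  for (i in 1:100) {
    gen <- ape::rtree(6, br = function(n) runif(n, 0.1, 1))
    d <- ape::cophenetic.phylo(gen)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tr <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
    back <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(back, d, tolerance = 1e-9)
  }
})

test_that("NJ is invariant to label order and handles 3 taxa exactly", {
  d3 <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d3)
  # three-point formulas: bx=(d_xy+d_xz-d_yz)/2 etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["x"]), 1)
  expect_equal(unname(bl["y"]), 2)
  expect_equal(unname(bl["z"]), 7)
  perm <- c("z", "x", "y")
  tr2 <- neighbor_joining(d3[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(tr, tr2)), 0)
  expect_error(neighbor_joining(d3[1:2, 1:2]), "at least 3")
})

test_that("clade membership checks respect tree splits", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  expect_true(clade_check(tr, "a", "b")) # cherry
  expect_true(clade_check(tr, "e", c("c", "d")))
  expect_false(clade_check(tr, "a", "c"))
  expect_false(clade_check(tr, "a", c("c", "d"))) # a alone on its side
  expect_error(clade_check(tr, "zz", "a"), "unknown label")
})

test_that("zero substitution probability copies the root everywhere", {
  tree <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  seqs <- evolve_sequences(tree, 200, seed = 53)
  expect_true(all(seqs == attr(seqs, "root")))
  expect_error(evolve_sequences(tree, 100, rate = 0.8), "0.75")
})

test_that("sequence evolution along a clade tree is recoverable by NJ", {
  nwk <- "((a:0.03,b:0.03):0.08,(c:0.03,d:0.03):0.08);"
  tree <- ape::read.tree(text = nwk)
  set.seed(54)
  hits <- replicate(20, {
    seqs <- evolve_sequences(tree, 20000)
    profs <- lapply(names(seqs), function(n) {
      kmer_profile(seqs[[n]], 17, label = n)
    })
    tr <- neighbor_joining(aaf_distance_matrix(profs))
    clade_check(tr, "a", "b") && clade_check(tr, "c", "d")
  })
  expect_gte(mean(hits), 0.95)
})

test_that("nuclear and organellar trees place the focal taxon discordantly", {
  bundle <- simulate_discordance_bundle(seed = 55, length = 8000)
  tree_of <- function(seqs) {
    profs <- lapply(names(seqs), function(n) {
      kmer_profile(seqs[[n]], 17, label = n)
    })
    neighbor_joining(aaf_distance_matrix(profs))
  }
  nuc <- tree_of(bundle$nuclear)
  org <- tree_of(bundle$organellar)
  expect_true(clade_check(nuc, bundle$focal, bundle$clades$east_asian))
  expect_false(clade_check(nuc, bundle$focal, bundle$clades$north_american))
  expect_true(clade_check(org, bundle$focal, bundle$clades$north_american))
  expect_false(clade_check(org, bundle$focal, bundle$clades$east_asian))
})
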