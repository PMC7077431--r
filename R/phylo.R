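#' Canonical k-mer profile of a sequence set
#'
#' Collects the set of canonical k-mers (lexicographic minimum of each
#' k-mer and its reverse complement) over all sequences of a FASTA file
#' or in-memory sequence set, the alignment-free representation used
#' for whole-genome distance trees. k-mers containing non-ACGT symbols
#' are skipped.
#'
#' @param x path to a (multi-record, possibly line-wrapped) FASTA file,
#'   a [Biostrings::DNAStringSet], or a character vector of sequences.
#' @param k odd k-mer size (default 25).
#' @param label profile label; defaults to the file base name.
#' @return object of class `kmer_profile`: list with `label`, `k`,
#'   `kmers` (character set) and `total_count` (k-mer instances seen).
#' @export
kmer_profile <- function(x, k = 25, label = NULL) {
  stopifnot(k %% 2 == 1, k >= 3)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    if (is.null(label)) {
      label <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(x))
    }
    x <- Biostrings::readDNAStringSet(x)
  }
  seqs <- toupper(as.character(x))
  if (is.null(label)) label <- "profile"
  all_kmers <- character(0)
  total <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kf <- substring(s, starts, starts + k - 1L)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gsub("[^ACGT]", "N", s))))
    kr <- substring(rc, starts, starts + k - 1L)
    krc <- rev(kr) # krc[i] is the reverse complement of kf[i]
    ok <- !grepl("[^ACGT]", kf)
    if (!any(ok)) next
    canon <- pmin(kf[ok], krc[ok])
    total <- total + length(canon)
    all_kmers <- c(all_kmers, canon)
  }
  kmers <- unique(all_kmers)
  if (length(kmers) == 0) stop("no usable sequence for k-mer profile")
  structure(list(label = label, k = k, kmers = kmers,
                 total_count = total),
            class = "kmer_profile")
}

#' Alignment-free k-mer distance between two profiles
#'
#' The shared-fraction logarithmic distance of the assembly-and-
#' alignment-free (AAF) approach: F = |A intersect B| / min(|A|, |B|)
#' and d = -(1/k) ln F. Disjoint profiles (F = 0) map to the cap
#' `d_max`.
#'
#' @param a,b `kmer_profile` objects with equal `k`.
#' @param d_max distance assigned when no k-mer is shared (default 1.0).
#' @return non-negative distance (0 iff identical k-mer sets).
#' @export
aaf_distance <- function(a, b, d_max = 1.0) {
  stopifnot(inherits(a, "kmer_profile"), inherits(b, "kmer_profile"))
  if (a$k != b$k) stop("k mismatch: ", a$k, " vs ", b$k)
  f <- length(intersect(a$kmers, b$kmers)) /
    min(length(a$kmers), length(b$kmers))
  if (f == 0) return(d_max)
  min(d_max, -(1 / a$k) * log(f))
}

#' Pairwise AAF distance matrix from k-mer profiles
#'
#' @param profiles list of `kmer_profile` objects (>= 3, unique labels).
#' @param d_max cap for disjoint profiles.
#' @return symmetric labelled distance matrix with zero diagonal.
#' @export
aaf_distance_matrix <- function(profiles, d_max = 1.0) {
  n <- length(profiles)
  stopifnot(n >= 2)
  labs <- vapply(profiles, function(p) p$label, character(1))
  if (anyDuplicated(labs)) stop("profile labels must be unique")
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- aaf_distance(profiles[[i]], profiles[[j]],
                                         d_max)
    }
  }
  d
}

#' Convert a similarity matrix to a distance matrix
#'
#' For similarity matrices derived from averaged alignment hit scores:
#' d(i, j) = 1 - s(i, j) / max(s), with the diagonal forced to zero.
#'
#' @param s symmetric non-negative similarity matrix with positive
#'   diagonal and labelled dimnames.
#' @param tol asymmetry tolerance (default 1e-6).
#' @return symmetric distance matrix, zero diagonal.
#' @export
similarity_to_distance <- function(s, tol = 1e-6) {
  s <- as.matrix(s)
  stopifnot(nrow(s) == ncol(s), all(s >= 0), all(diag(s) > 0))
  if (max(abs(s - t(s))) > tol) stop("similarity matrix is asymmetric")
  d <- 1 - s / max(s)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the given pairwise distances (exact on
#' additive matrices). Negative branch lengths, which NJ can produce on
#' noisy input, are clamped to zero and flagged.
#'
#' @param d symmetric labelled distance matrix, n >= 3, zero diagonal.
#' @return an unrooted [ape::phylo] tree; attribute `"clamped"` is TRUE
#'   when any branch length was negative before clamping.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  stopifnot(!is.null(rownames(d)), max(abs(d - t(d))) < 1e-12,
            all(abs(diag(d)) < 1e-12))
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- any(neg)
  tr
}

#' Does a taxon sort with a given group?
#'
#' TRUE iff some edge bisection of the unrooted tree places the focal
#' taxon plus all group members on one side and every remaining leaf on
#' the other — i.e. \{focal\} union group is a split of the tree.
#'
#' @param tree an [ape::phylo] tree.
#' @param focal_label focal leaf label.
#' @param group_labels labels of the group (non-empty, excluding the
#'   focal taxon).
#' @return logical.
#' @export
clade_check <- function(tree, focal_label, group_labels) {
  stopifnot(inherits(tree, "phylo"), length(group_labels) >= 1)
  labs <- tree$tip.label
  unknown <- setdiff(c(focal_label, group_labels), labs)
  if (length(unknown)) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  target <- labs %in% c(focal_label, group_labels)
  sp <- as.matrix(phangorn::as.splits(ape::unroot(tree)))
  colnames(sp) <- NULL
  for (i in seq_len(nrow(sp))) {
    side <- sp[i, ] == 1
    if (identical(unname(side), target) ||
        identical(unname(!side), target)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Evolve sequences along a tree by per-branch substitution
#'
#' Jukes-Cantor-style site-independent simulation: a uniform-random
#' root sequence mutates along each branch, each site substituting with
#' the branch's probability to one of the three other bases uniformly.
#' Branch substitution probabilities come from the tree's edge lengths
#' (or a single `rate` overriding them) and must lie in \[0, 0.75).
#'
#' @param tree an [ape::phylo] with edge lengths interpreted as per-site
#'   substitution probabilities.
#' @param length sequence length in bp.
#' @param seed optional integer seed.
#' @param rate optional scalar replacing every branch probability.
#' @return named character vector of tip sequences; the root sequence
#'   is attached as attribute `"root"`.
#' @export
evolve_sequences <- function(tree, length, seed = NULL, rate = NULL) {
  stopifnot(inherits(tree, "phylo"), length >= 1)
  n_sites <- as.integer(length)
  length <- NULL # avoid masking base::length below
  probs <- if (is.null(rate)) tree$edge.length else {
    rep(rate, nrow(tree$edge))
  }
  if (is.null(probs)) stop("tree has no branch substitution probabilities")
  if (any(probs < 0) || any(probs >= 0.75)) {
    stop("substitution probabilities must lie in [0, 0.75)")
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  seqs[[root]] <- sample(bases, n_sites, replace = TRUE)
  # preorder: reverse postorder guarantees parents before children
  edge_order <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2])
  edge_idx <- match(edge_order, tree$edge[, 2])
  for (e in edge_idx) {
    par <- tree$edge[e, 1]
    chi <- tree$edge[e, 2]
    s <- seqs[[par]]
    hit <- which(stats::runif(n_sites) < probs[e])
    if (length(hit)) {
      cur <- s[hit]
      new <- vapply(cur, function(b) sample(setdiff(bases, b), 1),
                    character(1))
      s[hit] <- new
    }
    seqs[[chi]] <- s
  }
  out <- vapply(seq_len(n_tip), function(i) {
    paste(seqs[[i]], collapse = "")
  }, character(1))
  names(out) <- tree$tip.label
  attr(out, "root") <- paste(seqs[[root]], collapse = "")
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}
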