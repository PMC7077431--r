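#' Simulate a Kingman coalescent genealogy
#'
#' Generates a random binary genealogy for `n` haplotypes under the
#' standard neutral coalescent. Time is measured in units of 2N
#' generations: while `k` lineages remain, the waiting time to the next
#' coalescence is Exponential with rate k(k-1)/2, and the coalescing pair
#' is chosen uniformly.
#'
#' Nodes 1..n are leaves (time 0); node n+j is the j-th coalescence.
#'
#' @param n number of haplotypes (>= 2).
#' @param seed optional integer seed; if supplied, [set.seed()] is called.
#' @return an object of class `coal_tree`: a list with `n`, `parent`
#'   (parent index per node, 0 for the root) and `time` (node ages).
#' @export
simulate_genealogy <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("degenerate sample: need at least 2 haplotypes")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  active <- seq_len(n)
  t <- 0
  for (k in seq(n, 2L)) {
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pair <- sample(length(active), 2L)
    new_node <- 2L * n - k + 1L
    parent[active[pair]] <- new_node
    time[new_node] <- t
    active <- c(active[-pair], new_node)
  }
  structure(list(n = n, parent = parent, time = time), class = "coal_tree")
}

#' Reshape a genealogy under a selection regime
#'
#' Emulates the genealogical footprint of the three site-frequency-spectrum
#' regimes the sweep screen must distinguish:
#' \describe{
#'   \item{neutral}{identity.}
#'   \item{sweep}{node times are compressed toward a scaled-down root:
#'     with tree height T, t -> sweep_scale * T * (t/T)^sweep_scale.
#'     The height shrinks by `sweep_scale` (reduced diversity, smaller
#'     S) while relative coalescence times are pushed toward the root
#'     (star-like genealogy, excess rare variants, negative Tajima's
#'     D) - the joint footprint of a recent selective sweep. Plain
#'     uniform time scaling would shorten the tree without changing
#'     its shape and thus leave the site-frequency spectrum, and D,
#'     unchanged in expectation.}
#'   \item{balancing}{the deepest coalescence time multiplied by
#'     `balancing_boost` >= 1, lengthening the basal branches and
#'     enriching intermediate-frequency variants (positive Tajima's D),
#'     the structure expected for an interspecific-hybrid pool.}
#' }
#'
#' @param tree a `coal_tree`.
#' @param regime one of `"neutral"`, `"sweep"`, `"balancing"`.
#' @param sweep_scale tree-height compression factor in (0, 1].
#' @param balancing_boost root-branch stretch factor >= 1.
#' @return the modified `coal_tree`.
#' @export
apply_regime <- function(tree, regime = c("neutral", "sweep", "balancing"),
                         sweep_scale = 0.1, balancing_boost = 5) {
  stopifnot(inherits(tree, "coal_tree"))
  regime <- match.arg(regime)
  if (regime == "sweep") {
    stopifnot(sweep_scale > 0, sweep_scale <= 1)
    height <- max(tree$time)
    if (height > 0) {
      tree$time <- sweep_scale * height * (tree$time / height)^sweep_scale
      # leaves stay at time 0
      tree$time[seq_len(tree$n)] <- 0
    }
  } else if (regime == "balancing") {
    stopifnot(balancing_boost >= 1)
    root <- 2L * tree$n - 1L
    tree$time[root] <- tree$time[root] * balancing_boost
  }
  tree
}

#' Leaves descending from each node of a genealogy
#' @noRd
coal_descendants <- function(tree) {
  n_nodes <- 2L * tree$n - 1L
  desc <- vector("list", n_nodes)
  for (i in seq_len(tree$n)) desc[[i]] <- i
  # children are always created before their parent
  for (i in seq_len(n_nodes - 1L)) {
    p <- tree$parent[i]
    desc[[p]] <- c(desc[[p]], desc[[i]])
  }
  lapply(desc, sort)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places Poisson(theta/2 x branch length) mutations on each branch; every
#' mutation creates a new segregating column whose derived allele is
#' carried by exactly the leaves below that branch. Site positions are
#' drawn uniformly without replacement from `0:(length-1)` (0-based) and
#' sorted, so the infinite-sites assumption (no recurrent mutation) holds
#' by construction.
#'
#' @param tree a `coal_tree`.
#' @param theta scaled mutation rate 4N*mu*L for the gene (> 0).
#' @param seed optional integer seed.
#' @param length gene length in bp; positions are drawn within it.
#' @return an object of class `haplotype_set`: list with `hap`
#'   (haplotype x site 0/1 matrix), `positions` (0-based, strictly
#'   increasing) and `length`.
#' @export
drop_mutations <- function(tree, theta, seed = NULL, length = 2000L) {
  stopifnot(inherits(tree, "coal_tree"))
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- tree$n
  n_nodes <- 2L * n - 1L
  branch_len <- tree$time[tree$parent[-n_nodes]] - tree$time[-n_nodes]
  n_mut <- stats::rpois(n_nodes - 1L, lambda = theta / 2 * branch_len)
  total <- sum(n_mut)
  if (total > length) {
    stop("gene too short: ", total, " mutations on ", length, " bp")
  }
  hap <- matrix(0L, nrow = n, ncol = total)
  if (total > 0) {
    desc <- coal_descendants(tree)
    col <- 0L
    for (b in seq_len(n_nodes - 1L)) {
      if (n_mut[b] > 0) {
        for (j in seq_len(n_mut[b])) {
          col <- col + 1L
          hap[desc[[b]], col] <- 1L
        }
      }
    }
    pos <- sort(sample.int(length, total) - 1L)
  } else {
    pos <- integer(0)
  }
  structure(list(hap = hap, positions = pos, length = as.integer(length)),
            class = "haplotype_set")
}

#' Pair haplotypes into diploid genotypes
#'
#' Random pairing without inbreeding: haplotype rows are permuted, then
#' consecutive pairs form diploids. Genotypes are derived-allele counts.
#'
#' @param hs a `haplotype_set` with an even number of haplotypes.
#' @param seed optional integer seed for the pairing permutation.
#' @return sites x diploids integer matrix with entries 0/1/2.
#' @export
pair_diploids <- function(hs, seed = NULL) {
  stopifnot(inherits(hs, "haplotype_set"))
  n_hap <- nrow(hs$hap)
  if (n_hap %% 2 != 0) stop("odd number of haplotypes cannot be paired")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_hap)
  h <- hs$hap[perm, , drop = FALSE]
  odd <- seq(1L, n_hap, by = 2L)
  g <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  t(g) # sites x diploids
}
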