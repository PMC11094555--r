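# shared in-code fixtures for the suite

# a Neighborhood whose genes carry the given label sets (singletons or
# character vectors) in one namespace, at fixed non-overlapping coordinates
nbhFromLabels <- function(labels, id = "n1", anchorIndex = 1L,
                          namespace = "Pfam", strands = NULL) {
  n <- length(labels)
  starts <- seq(100L, by = 500L, length.out = n)
  ends <- starts + 299L
  if (is.null(strands)) strands <- rep("+", n)
  gr <- geneRanges("ctg", paste0(id, "_g", seq_len(n)), starts, ends,
                   strands,
                   labels = stats::setNames(list(lapply(labels, as.character)),
                                            namespace))
  neighborhood(id, paste0(id, "_g", anchorIndex), gr,
               windowStart = 1L, windowEnd = max(ends) + 100L,
               genomeId = paste0("gen_", id), contigId = "ctg")
}

# random label vector over a small alphabet, possibly with empty or
# multi-label sets
randLabelVector <- function(maxLen = 6, alphabet = c("A", "B", "C", "D")) {
  n <- sample(seq_len(maxLen), 1)
  lapply(seq_len(n), function(i) {
    k <- sample(0:2, 1, prob = c(0.15, 0.7, 0.15))
    if (k == 0) character(0) else sample(alphabet, k)
  })
}

# two planted core-operon variants with disjoint label alphabets,
# interleaved into one set; returns the set plus variant membership
plantedVariantsSet <- function(seed, nPerVariant = 4, inversionProb = 0) {
  sA <- generateNeighborhoodSet(fixtureSpec(
    nNeighborhoods = nPerVariant, coreLabels = sprintf("PF%05d", 101:105),
    inversionProb = inversionProb, seed = seed), idPrefix = "va")
  sB <- generateNeighborhoodSet(fixtureSpec(
    nNeighborhoods = nPerVariant, coreLabels = sprintf("PF%05d", 201:205),
    inversionProb = inversionProb, seed = seed + 100000L), idPrefix = "vb")
  nbhs <- list()
  membership <- integer(0)
  for (i in seq_len(nPerVariant)) {   # interleave A/B
    nbhs <- c(nbhs, list(sA[[i]], sB[[i]]))
    membership <- c(membership, 1L, 2L)
  }
  list(set = neighborhoodSet(nbhs, activeNamespace = "Pfam"),
       membership = membership)
}

# leaf order splits members into contiguous blocks with zero within-block
# distance
recoversVariants <- function(ordering, membership) {
  ord <- leafOrder(ordering)
  runs <- rle(membership[ord])
  if (length(runs$lengths) != 2L) return(FALSE)
  D <- distanceMatrix(ordering)
  for (v in unique(membership)) {
    idx <- which(membership == v)
    if (max(D[idx, idx]) > 1e-9) return(FALSE)
  }
  TRUE
}
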