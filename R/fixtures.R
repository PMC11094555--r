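## small fixed lineage table used by the generators
.FIXTURE_LINEAGES <- c(
  "d__Archaea;p__Halobacteriota;c__Methanosarcinia;o__Methanosarcinales;f__Methanosarcinaceae;g__Methanosarcina;s__Methanosarcina barkeri",
  "d__Archaea;p__Methanobacteriota;c__Methanobacteria;o__Methanobacteriales;f__Methanobacteriaceae;g__Methanobacterium;s__Methanobacterium formicicum",
  "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Enterobacterales;f__Pseudoalteromonadaceae;g__Pseudoalteromonas;s__Pseudoalteromonas tunicata",
  "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Enterobacterales;f__Colwelliaceae;g__Cognaticolwellia;s__Cognaticolwellia mytili",
  "d__Bacteria;p__Bacillota;c__Bacilli;o__Bacillales;f__Bacillaceae;g__Bacillus;s__Bacillus subtilis",
  "d__Bacteria;p__Actinomycetota;c__Actinomycetes;o__Mycobacteriales;f__Mycobacteriaceae;g__Mycobacterium;s__Mycobacterium smegmatis")

#' Specification for a synthetic neighborhood fixture
#'
#' Describes a set of synthetic gene neighborhoods with planted structure:
#' every neighborhood gets an anchor carrying `coreLabels[1]`, a stated
#' fraction additionally carry the full ordered core block (emulating a
#' conserved operon), and the core block may be reversed (emulating an
#' inverted neighborhood) or interrupted by an insertion of genes with
#' labels unique to that neighborhood (emulating a species-specific
#' insertion). Flanking noise genes draw labels from `noiseLabelPool`
#' (or stay unannotated when the pool is empty). All randomness flows
#' from the single `seed`; equal specs produce byte-identical outputs.
#'
#' @param nNeighborhoods number of neighborhoods (default 12).
#' @param genesPerNeighborhood inclusive integer range for the total gene
#'   count per neighborhood (default `c(8, 14)`).
#' @param coreLabels ordered labels of the conserved core block (default
#'   five Pfam-style labels); the first is the anchor's label.
#' @param coreFraction fraction of neighborhoods carrying the full core
#'   block (default 1).
#' @param noiseLabelPool label alphabet for non-core genes; `character(0)`
#'   (the default) leaves them unannotated.
#' @param inversionProb probability that a neighborhood's core block is
#'   reversed (default 0).
#' @param insertionProb probability of a planted insertion inside the core
#'   block (default 0).
#' @param namespace annotation namespace the labels live in (default
#'   `"Pfam"`).
#' @param seed integer seed driving all randomness (default 1).
#' @return a validated list of class `"FixtureSpec"`.
#' @seealso [generateNeighborhoodSet()]
#' @export
fixtureSpec <- function(nNeighborhoods = 12,
                        genesPerNeighborhood = c(8, 14),
                        coreLabels = c("PF00100", "PF00200", "PF00300",
                                       "PF00400", "PF00500"),
                        coreFraction = 1,
                        noiseLabelPool = character(0),
                        inversionProb = 0,
                        insertionProb = 0,
                        namespace = "Pfam",
                        seed = 1) {
  stopifnot(nNeighborhoods >= 1,
            length(genesPerNeighborhood) == 2L,
            genesPerNeighborhood[1] >= length(coreLabels),
            genesPerNeighborhood[1] <= genesPerNeighborhood[2],
            coreFraction >= 0, coreFraction <= 1,
            inversionProb >= 0, inversionProb <= 1,
            insertionProb >= 0, insertionProb <= 1,
            length(coreLabels) >= 1)
  structure(list(nNeighborhoods = as.integer(nNeighborhoods),
                 genesPerNeighborhood = as.integer(genesPerNeighborhood),
                 coreLabels = coreLabels, coreFraction = coreFraction,
                 noiseLabelPool = noiseLabelPool,
                 inversionProb = inversionProb,
                 insertionProb = insertionProb,
                 namespace = namespace, seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Generate a synthetic NeighborhoodSet (and optionally files on disk)
#'
#' Realizes a [fixtureSpec()]: builds one synthetic contig per
#' neighborhood (non-overlapping genes, 300-1500 bp, 50-200 bp intergenic
#' gaps, random strands for non-core genes, taxonomy cycled from a small
#' fixed lineage table) and extracts the neighborhood around the planted
#' anchor with [extractNeighborhood()]. With `dir`, the underlying genomes
#' are also written as `fixture.gff3` and `fixture.gbk` and the set as
#' `fixture.csv`, all encoding the same genes.
#'
#' @param spec a [fixtureSpec()].
#' @param dir optional directory for GFF3/GenBank/CSV copies.
#' @param idPrefix prefix for neighborhood/contig identifiers.
#' @return a [NeighborhoodSet-class] with `activeNamespace` set from the
#'   spec; when `dir` is given, the file paths are attached as attribute
#'   `"files"`.
#' @export
generateNeighborhoodSet <- function(spec, dir = NULL, idPrefix = "nbh") {
  stopifnot(inherits(spec, "FixtureSpec"))
  withr::with_seed(spec$seed, {
    records <- vector("list", spec$nNeighborhoods)
    anchors <- character(spec$nNeighborhoods)
    nbhIds <- sprintf("%s%03d", idPrefix, seq_len(spec$nNeighborhoods))
    hasCore <- stats::runif(spec$nNeighborhoods) <= spec$coreFraction
    for (i in seq_len(spec$nNeighborhoods)) {
      nGenes <- spec$genesPerNeighborhood[1] - 1L +
        sample.int(spec$genesPerNeighborhood[2] -
                     spec$genesPerNeighborhood[1] + 1L, 1L)
      core <- length(spec$coreLabels)
      labels <- vector("list", nGenes)
      strands <- sample(c("+", "-"), nGenes, replace = TRUE)
      if (hasCore[i]) {
        coreAt <- sample(seq_len(nGenes - core + 1L), 1L)
        coreIdx <- seq(coreAt, coreAt + core - 1L)
        coreLabs <- spec$coreLabels
        coreStrand <- "+"
        if (stats::runif(1) <= spec$inversionProb) {
          coreLabs <- base::rev(coreLabs)
          coreStrand <- "-"
        }
        labels[coreIdx] <- as.list(coreLabs)
        strands[coreIdx] <- coreStrand
        anchorIdx <- coreIdx[match(spec$coreLabels[1], coreLabs)]
        if (core >= 3L && stats::runif(1) <= spec$insertionProb) {
          # plant 1-2 genes with neighborhood-unique labels inside the core
          nIns <- sample(1:2, 1L)
          at <- sample(seq(coreIdx[1], coreIdx[core] - 1L), 1L)
          insLabels <- lapply(seq_len(nIns), function(j)
            sprintf("INS%03d_%d", i, j))
          labels <- append(labels, insLabels, after = at)
          strands <- append(strands, sample(c("+", "-"), nIns,
                                            replace = TRUE), after = at)
          nGenes <- nGenes + nIns
          if (anchorIdx > at) anchorIdx <- anchorIdx + nIns
        }
      } else {
        anchorIdx <- sample(seq_len(nGenes), 1L)
        labels[[anchorIdx]] <- spec$coreLabels[1]
      }
      noise <- which(vapply(labels, is.null, logical(1)))
      for (j in noise) {
        labels[[j]] <- if (length(spec$noiseLabelPool))
          sample(spec$noiseLabelPool, 1L) else character(0)
      }
      lens <- sample(300:1500, nGenes, replace = TRUE)
      gaps <- sample(50:200, nGenes, replace = TRUE)
      startsBp <- 100L + cumsum(c(0L, utils::head(lens + gaps, -1L)))
      endsBp <- startsBp + lens - 1L
      contigLength <- endsBp[nGenes] + sample(100:500, 1L)
      geneIds <- sprintf("%s_g%02d", nbhIds[i], seq_len(nGenes))
      products <- ifelse(lengths(labels) > 0,
                         paste0(vapply(labels, function(x)
                           if (length(x)) x[1] else "", character(1)),
                           " family protein"),
                         "hypothetical protein")
      labs <- stats::setNames(list(labels), spec$namespace)
      gr <- geneRanges(nbhIds[i], geneIds, startsBp, endsBp, strands,
                       products, labs)
      records[[i]] <- genomeRecord(
        nbhIds[i], gr, contigLength = contigLength,
        genomeId = sprintf("genome%03d", i),
        taxonomy = .FIXTURE_LINEAGES[((i - 1L) %%
                                        length(.FIXTURE_LINEAGES)) + 1L])
      anchors[i] <- geneIds[anchorIdx]
    }
    nbhs <- lapply(seq_along(records), function(i)
      extractNeighborhood(records[[i]], anchors[i],
                          windowBp = records[[i]]@contigLength,
                          neighborhoodId = nbhIds[i]))
    s <- neighborhoodSet(nbhs, activeNamespace = spec$namespace)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- c(gff3 = file.path(dir, "fixture.gff3"),
                 genbank = file.path(dir, "fixture.gbk"),
                 csv = file.path(dir, "fixture.csv"))
      writeGff3(records, files[["gff3"]])
      writeGenBank(records, files[["genbank"]])
      writeNeighborhoodCsv(s, files[["csv"]])
      attr(s, "files") <- files
    }
    s
  })
}

#' Generate a synthetic homology hit table
#'
#' E-values are log-uniform over `[1e-50, 1]`, identities uniform on
#' `[20, 100]`, coverages uniform on `[40, 100]`, bitscores uniform on
#' `[50, 500]`, and subject taxonomies drawn from a small fixed lineage
#' table. Deterministic under `seed`.
#'
#' @param n number of hits.
#' @param seed integer seed.
#' @return hit data.frame (see [hit-tables]).
#' @export
generateHits <- function(n, seed = 1) {
  stopifnot(n >= 0)
  if (n == 0)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pct_identity = numeric(0), evalue = numeric(0),
                      bitscore = numeric(0), q_cov = numeric(0),
                      s_cov = numeric(0), subject_taxonomy = character(0),
                      stringsAsFactors = FALSE))
  withr::with_seed(as.integer(seed), {
    data.frame(
      query_id = rep("query1", n),
      subject_id = sprintf("subj%05d", seq_len(n)),
      pct_identity = stats::runif(n, 20, 100),
      evalue = 10^stats::runif(n, -50, 0),
      bitscore = stats::runif(n, 50, 500),
      q_cov = stats::runif(n, 40, 100),
      s_cov = stats::runif(n, 40, 100),
      subject_taxonomy = sample(.FIXTURE_LINEAGES, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Generate a random annotated genome (for property testing)
#'
#' A single contig with non-overlapping genes and per-gene singleton
#' labels; used to exercise the window-extraction rule on arbitrary
#' geometries. Deterministic under `seed`.
#'
#' @param nGenes number of genes (default 30).
#' @param seed integer seed.
#' @param namespace annotation namespace for the labels.
#' @return a [GenomeRecord-class].
#' @export
generateGenome <- function(nGenes = 30, seed = 1, namespace = "Pfam") {
  withr::with_seed(as.integer(seed), {
    lens <- sample(200:2500, nGenes, replace = TRUE)
    gaps <- sample(10:800, nGenes, replace = TRUE)
    startsBp <- 50L + cumsum(c(0L, utils::head(lens + gaps, -1L)))
    endsBp <- startsBp + lens - 1L
    labels <- stats::setNames(
      list(lapply(seq_len(nGenes), function(i)
        sprintf("PF%05d", sample(1:300, 1L)))), namespace)
    gr <- geneRanges("ctg1", sprintf("g%03d", seq_len(nGenes)),
                     startsBp, endsBp,
                     sample(c("+", "-"), nGenes, replace = TRUE),
                     labels = labels)
    genomeRecord("ctg1", gr, contigLength = endsBp[nGenes] + 200L,
                 genomeId = sprintf("sim%d", seed))
  })
}
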