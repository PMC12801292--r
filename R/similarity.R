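#' @include AllClasses.R chem-io.R
NULL

#' Extended-connectivity (circular) fingerprints
#'
#' ECFP fingerprints with a default radius of 2 (ECFP4) and 2048 bits.
#' Fingerprints are computed with OpenBabel's ECFP implementation (native
#' width 4096 bits) and folded by OR-ing equal blocks down to `nBits`.
#' Bits are deterministic for a given canonical structure and invariant to
#' the input atom ordering; note that absolute bit positions are specific
#' to the generating implementation, as with every hashed fingerprint.
#'
#' @param x molecules: a named character vector of SMILES, or a
#'   `ChemmineR::SDFset`.
#' @param radius circular neighbourhood radius (0-5; default 2).
#' @param nBits folded fingerprint length; a power of two <= 4096
#'   (default 2048).
#' @return a [FingerprintSet-class].
#' @examples
#' \donttest{
#' fps <- ecfpFingerprints(c(benzene = "c1ccccc1", toluene = "Cc1ccccc1"))
#' tanimoto(fingerprintBits(fps)[1, ], fingerprintBits(fps)[2, ])
#' }
#' @export
ecfpFingerprints <- function(x, radius = 2, nBits = 2048) {
  .assert(radius %in% 0:5, "radius must be in 0..5")
  .assert(nBits >= 1 && bitwAnd(nBits, nBits - 1L) == 0 && nBits <= 4096,
          "nBits must be a power of two <= 4096")
  if (is.character(x)) x <- smilesToSDFset(x)
  .assert(is(x, "SDFset"), "x must be SMILES or an SDFset")
  fp <- ChemmineR::fingerprintOB(x, paste0("ECFP", 2L * radius))
  m <- matrix(as.logical(ChemmineR::as.matrix(fp)), nrow = length(x))
  native <- ncol(m)
  if (nBits < native) {
    fold <- matrix(FALSE, nrow(m), nBits)
    for (b in seq_len(native / nBits))
      fold <- fold | m[, ((b - 1L) * nBits + 1L):(b * nBits), drop = FALSE]
    m <- fold
  }
  new("FingerprintSet", ids = ChemmineR::cid(x), bits = m,
      radius = as.integer(radius), nBits = as.integer(nBits))
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bits. Two all-zero fingerprints
#' have, by convention, similarity 1.0 (identical objects).
#'
#' @param a,b logical bit vectors of equal length.
#' @return coefficient in \[0, 1\].
#' @examples
#' tanimoto(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))  # 0.5
#' @export
tanimoto <- function(a, b) {
  .assert(length(a) == length(b), "fingerprint lengths differ: ",
          length(a), " vs ", length(b))
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(1.0)
  sum(a & b) / un
}

#' Pairwise Tanimoto similarity matrix
#'
#' Full symmetric matrix with unit diagonal. When `cluster = TRUE` an
#' average-linkage hierarchical clustering order on `1 - similarity` is
#' attached as `attr(, "clusterOrder")` for heat-map display.
#'
#' @param fps a [FingerprintSet-class] with >= 2 compounds, or molecule
#'   input accepted by [ecfpFingerprints()].
#' @param cluster attach a hierarchical-clustering display order.
#' @return numeric matrix with compound ids as dimnames.
#' @export
similarityMatrix <- function(fps, cluster = FALSE) {
  if (!is(fps, "FingerprintSet")) fps <- ecfpFingerprints(fps)
  n <- length(fps@ids)
  .assert(n >= 2, "need >= 2 molecules")
  b <- fps@bits * 1L
  common <- tcrossprod(b)                      # |A & B|
  on <- rowSums(b)
  un <- outer(on, on, "+") - common            # |A | B|
  sim <- ifelse(un == 0, 1, common / pmax(un, 1))
  dimnames(sim) <- list(fps@ids, fps@ids)
  if (cluster && n >= 3) {
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    attr(sim, "clusterOrder") <- hc$order
  }
  sim
}

#' Save a clustered similarity heat map
#'
#' @param sim matrix from [similarityMatrix()].
#' @param path PNG output path.
#' @return `path`, invisibly.
#' @export
similarityHeatmap <- function(sim, path) {
  grDevices::png(path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  stats::heatmap(sim, symm = TRUE, scale = "none",
                 col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE))
  invisible(path)
}

#' Leader (sphere-exclusion) clustering with representative selection
#'
#' Compounds are processed in priority order (best consensus rank first).
#' Each unassigned compound becomes the leader of a new cluster and
#' captures every unassigned compound with Tanimoto similarity >= the
#' threshold; the leader — the best-ranked member of its cluster — is the
#' cluster representative. The representative list is capped at
#' `kRepresentatives` (best-ranked clusters first).
#'
#' @param fps a [FingerprintSet-class].
#' @param ranks optional named numeric vector (lower = better) giving the
#'   processing priority; default is the fingerprint order.
#' @param simThreshold Tanimoto threshold for cluster membership
#'   (default 0.6).
#' @param kRepresentatives cap on the number of representatives
#'   (default all clusters).
#' @return list with `assignments` (data.frame compound_id, cluster,
#'   is_representative) and `representatives` (character vector).
#' @export
clusterSelect <- function(fps, ranks = NULL, simThreshold = 0.6,
                          kRepresentatives = NULL) {
  ids <- fps@ids
  ord <- if (is.null(ranks)) seq_along(ids)
  else {
    .assert(all(ids %in% names(ranks)), "ranks missing for some compounds")
    order(ranks[ids], ids, method = "radix")
  }
  n <- length(ids)
  sim <- if (n >= 2) similarityMatrix(fps) else
    matrix(1, 1, 1, dimnames = list(ids, ids))
  cluster <- rep(NA_integer_, n)
  leaders <- integer()
  for (i in ord) {
    if (!is.na(cluster[i])) next
    leaders <- c(leaders, i)
    cl <- length(leaders)
    members <- which(is.na(cluster) & sim[i, ] >= simThreshold)
    cluster[unique(c(i, members))] <- cl
  }
  reps <- ids[leaders]
  if (!is.null(kRepresentatives))
    reps <- reps[seq_len(min(kRepresentatives, length(reps)))]
  list(assignments = data.frame(compound_id = ids, cluster = cluster,
                                is_representative = ids %in% reps,
                                stringsAsFactors = FALSE),
       representatives = reps)
}
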