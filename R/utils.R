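# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps generator functions pure.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deduplication key of an interaction: residue-level within each kind.
.interaction_key <- function(chain, resno, kind) {
  paste(trimws(chain), as.integer(resno), kind, sep = ":")
}

# Key including the hydrophobic subtype, for subtype-resolved models.
.interaction_key_sub <- function(chain, resno, kind, subtype) {
  paste(trimws(chain), as.integer(resno), kind, subtype, sep = ":")
}

.assert <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)

# Stable row ordering for interaction tables: chain, residue number, kind.
.order_interactions <- function(df) {
  df[order(df$chain, df$resno, df$kind, df$subtype, method = "radix"), ,
     drop = FALSE]
}

.empty_interactions <- function() {
  data.frame(chain = character(), resno = integer(), resname = character(),
             kind = character(), subtype = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

# Euclidean distances between two coordinate matrices (n x 3, m x 3).
.cross_dist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Unit normal of the best-fit plane through points (n x 3, n >= 3).
.plane_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(c0, nu = 0, nv = 3)
  sv$v[, 3]
}

# Angle (degrees) at vertex b for points a-b-c.
.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
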