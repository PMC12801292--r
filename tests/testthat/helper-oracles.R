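# Independent brute-force oracles used across the suite. These deliberately
# re-implement the detection criteria, AUC and rank-sum definitions with
# naive loops, separate from the package's vectorized code paths.

.o_dist <- function(a, b) sqrt(sum((a - b)^2))

.o_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u * u) * sum(v * v))))) * 180 / pi
}

# receptor N/O hydrogen-bond roles, re-derived independently
.o_receptor_role <- function(resname, atom, elem) {
  if (!elem %in% c("N", "O")) return("")
  key <- paste(resname, atom)
  donors <- c("ASN ND2", "GLN NE2", "LYS NZ", "ARG NE", "ARG NH1",
              "ARG NH2", "TRP NE1")
  acceptors <- c("ASN OD1", "GLN OE1", "ASP OD1", "ASP OD2", "GLU OE1",
                 "GLU OE2")
  both <- c("SER OG", "THR OG1", "TYR OH", "HIS ND1", "HIS NE2")
  if (atom == "N") return("donor")
  if (atom %in% c("O", "OXT")) return("acceptor")
  if (key %in% donors) return("donor")
  if (key %in% acceptors) return("acceptor")
  if (key %in% both) return("both")
  "both"
}

.o_ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

# Newell's method for a ring plane normal (independent of the package's
# SVD-based fit).
.o_normal <- function(xyz) {
  n <- c(0, 0, 0)
  k <- nrow(xyz)
  for (i in seq_len(k)) {
    p <- xyz[i, ]; q <- xyz[i %% k + 1, ]
    n <- n + c((p[2] - q[2]) * (p[3] + q[3]),
               (p[3] - q[3]) * (p[1] + q[1]),
               (p[1] - q[1]) * (p[2] + q[2]))
  }
  n / sqrt(sum(n * n))
}

# all simple cycles of length 5 or 6, by DFS over the bond list
.o_ligand_rings <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(list())
  n <- length(mol@elements)
  adj <- lapply(seq_len(n), function(i)
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1]))
  found <- list(); seen <- character()
  path <- integer()
  dfs <- function(start, cur) {
    path[[length(path) + 1L]] <<- cur
    for (w in adj[[cur]]) {
      if (w == start && length(path) >= 5) {
        key <- paste(sort(path), collapse = ",")
        if (!key %in% seen && length(path) <= 6) {
          seen <<- c(seen, key); found[[length(found) + 1L]] <<- path
        }
      } else if (!w %in% path && length(path) < 6 && w > start) {
        dfs(start, w)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  ords <- stats::setNames(b[, 3], paste(pmin(b[, 1], b[, 2]),
                                        pmax(b[, 1], b[, 2])))
  out <- list()
  for (ring in found) {
    k <- length(ring)
    rb <- vapply(seq_len(k), function(i)
      ords[[paste(min(ring[i], ring[i %% k + 1]),
                  max(ring[i], ring[i %% k + 1]))]], numeric(1))
    elems <- mol@elements[ring]
    heavy_nb <- vapply(ring, function(a)
      sum(mol@elements[adj[[a]]] != "H"), numeric(1))
    xyz <- mol@coords[ring, , drop = FALSE]
    if (anyNA(xyz)) next
    nv <- .o_normal(xyz)
    ctr <- colMeans(xyz)
    planar <- max(abs((xyz - rep(ctr, each = k)) %*% nv)) < 0.15
    if (all(rb == 4) ||
        (all(elems %in% c("C", "N")) && all(heavy_nb <= 3) && planar))
      out[[length(out) + 1L]] <- list(atoms = ring, centroid = ctr,
                                      normal = nv)
  }
  out
}

# literal all-pairs re-implementation of the interaction criteria;
# returns a sorted character vector of "chain:resno:kind/subtype" entries
oracle_profile_keys <- function(receptor, pose,
                                criteria = interactionCriteria()) {
  at <- receptorAtoms(receptor)
  bs <- bindingSite(receptor)
  if (nrow(bs))
    at <- at[paste(at$chain, at$resno) %in% paste(bs$chain, bs$resno), ]
  mol <- conformer(pose)
  n <- length(mol@elements)
  b <- mol@bonds
  adj <- lapply(seq_len(n), function(i)
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1]))
  hb <- list(); hp_alkyl <- character(); hp_pi <- character()
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1)
  lrings <- .o_ligand_rings(mol)
  lig_arom <- unique(unlist(lapply(lrings, `[[`, "atoms")))
  # receptor atoms that are members of a complete aromatic side-chain ring
  rec_arom <- logical(nrow(at))
  for (rk in unique(paste(at$chain, at$resno))) {
    sel <- paste(at$chain, at$resno) == rk
    rn <- at$resname[sel][1]
    if (!rn %in% names(.o_ring_atoms)) next
    for (ring_names in .o_ring_atoms[[rn]]) {
      idx <- which(sel & at$atom %in% ring_names)
      if (length(idx) == length(ring_names)) rec_arom[idx] <- TRUE
    }
  }
  for (li in seq_len(n)) {
    le <- mol@elements[li]
    lx <- mol@coords[li, ]
    if (anyNA(lx)) next
    nb_elems <- mol@elements[adj[[li]]]
    bond_sum <- sum(ifelse(b[b[, 1] == li | b[, 2] == li, 3] == 4, 1.5,
                           b[b[, 1] == li | b[, 2] == li, 3]))
    expl_h <- adj[[li]][mol@elements[adj[[li]]] == "H"]
    imp_h <- max(0, round((val[le] %||% 0) +
                            (le == "N") * mol@charges[li] - bond_sum))
    is_donor <- le %in% c("N", "O") && (length(expl_h) > 0 || imp_h > 0)
    is_acc <- le %in% c("N", "O") && !(le == "N" && mol@charges[li] > 0)
    is_apolar_c <- le == "C" && !any(nb_elems %in% c("N", "O", "S"))
    for (ri in seq_len(nrow(at))) {
      rx <- c(at$x[ri], at$y[ri], at$z[ri])
      d <- .o_dist(lx, rx)
      role <- .o_receptor_role(at$resname[ri], at$atom[ri], at$elem[ri])
      resk <- paste0(at$chain[ri], ":", at$resno[ri])
      if (is_donor && role %in% c("acceptor", "both") &&
          d <= criteria$hbDistMax) {
        ok <- TRUE
        hs <- expl_h[!is.na(mol@coords[expl_h, 1])]
        if (length(hs)) {
          angs <- vapply(hs, function(h)
            .o_angle(lx, mol@coords[h, ], rx), numeric(1))
          ok <- max(angs) >= criteria$hbAngleMin
        }
        if (ok) hb[[length(hb) + 1L]] <- c(resk, "donor")
      }
      if (is_acc && role %in% c("donor", "both") && d <= criteria$hbDistMax) {
        rh <- which(at$elem == "H")
        rh <- rh[vapply(rh, function(h)
          .o_dist(c(at$x[h], at$y[h], at$z[h]), rx) < 1.3, logical(1))]
        ok <- TRUE
        if (length(rh)) {
          angs <- vapply(rh, function(h)
            .o_angle(rx, c(at$x[h], at$y[h], at$z[h]), lx), numeric(1))
          ok <- max(angs) >= criteria$hbAngleMin
        }
        if (ok) hb[[length(hb) + 1L]] <- c(resk, "acceptor")
      }
      if (is_apolar_c && at$elem[ri] == "C" &&
          !at$atom[ri] %in% c("C", "CA") && d <= criteria$hpDistMax &&
          !(li %in% lig_arom && rec_arom[ri]))
        hp_alkyl <- c(hp_alkyl, resk)
    }
  }
  # pi stacking
  if (length(lrings)) {
    resk_all <- unique(paste(at$chain, at$resno))
    for (rk in resk_all) {
      sel <- paste(at$chain, at$resno) == rk
      rn <- at$resname[sel][1]
      if (!rn %in% names(.o_ring_atoms)) next
      for (ring_names in .o_ring_atoms[[rn]]) {
        idx <- which(sel & at$atom %in% ring_names)
        if (length(idx) != length(ring_names)) next
        xyz <- as.matrix(at[idx, c("x", "y", "z")])
        ctr <- colMeans(xyz); nv <- .o_normal(xyz)
        for (lr in lrings) {
          d <- .o_dist(lr$centroid, ctr)
          ang <- acos(min(1, abs(sum(lr$normal * nv)))) * 180 / pi
          if (d <= criteria$piDistMax &&
              (ang <= criteria$piParallelMax ||
                 (ang >= criteria$piTshapeMin &&
                    ang <= criteria$piTshapeMax)))
            hp_pi <- c(hp_pi, sub(" ", ":", rk))
        }
      }
    }
  }
  keys <- character()
  if (length(hb)) {
    m <- do.call(rbind, hb)
    for (rk in unique(m[, 1])) {
      roles <- unique(m[m[, 1] == rk, 2])
      keys <- c(keys, paste0(rk, ":HB/",
                             if (length(roles) > 1) "both" else roles))
    }
  }
  hp_res <- union(hp_alkyl, hp_pi)
  for (rk in hp_res) {
    st <- if (rk %in% hp_alkyl && rk %in% hp_pi) "mixed"
    else if (rk %in% hp_pi) "pi" else "alkyl"
    keys <- c(keys, paste0(rk, ":HP/", st))
  }
  sort(keys)
}

profile_keys_with_subtype <- function(profile) {
  df <- interactions(profile)
  if (!nrow(df)) return(character())
  sort(paste0(df$chain, ":", df$resno, ":", df$kind, "/", df$subtype))
}

# O(n^2) active-decoy pair counting with midrank ties
oracle_auc <- function(scores, labels) {
  act <- scores[as.logical(labels)]; dec <- scores[!as.logical(labels)]
  tot <- 0
  for (a in act) for (d in dec)
    tot <- tot + (a > d) + 0.5 * (a == d)
  tot / (length(act) * length(dec))
}

# brute-force rank-sum consensus: named rank vectors -> ordered compound ids
oracle_consensus_order <- function(rankings) {
  ids <- sort(unique(unlist(lapply(rankings, names))))
  sums <- vapply(ids, function(id) {
    s <- 0
    for (r in rankings)
      s <- s + if (id %in% names(r)) r[[id]] else length(r) + 1L
    s
  }, numeric(1))
  ids[order(sums, ids)]
}

# minimum RMSD over all element- and bond-preserving permutations
oracle_sym_rmsd <- function(a, b) {
  heavy <- which(a@elements != "H")
  ea <- a@elements[heavy]; eb <- b@elements[b@elements != "H"]
  xa <- a@coords[heavy, , drop = FALSE]
  xb <- b@coords[b@elements != "H", , drop = FALSE]
  bonds_of <- function(mol, keep) {
    bb <- mol@bonds
    bb <- bb[bb[, 1] %in% keep & bb[, 2] %in% keep, , drop = FALSE]
    idx <- match(seq_len(length(mol@elements)), keep)
    cbind(idx[bb[, 1]], idx[bb[, 2]], bb[, 3])
  }
  ba <- bonds_of(a, heavy)
  bb <- bonds_of(b, which(b@elements != "H"))
  bkey <- function(m) sort(paste(pmin(m[, 1], m[, 2]),
                                 pmax(m[, 1], m[, 2]), m[, 3]))
  best <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_along(ea))) {
    if (!identical(ea, eb[p])) next
    m2 <- cbind(match(bb[, 1], p), match(bb[, 2], p), bb[, 3])
    if (!identical(bkey(ba), bkey(m2))) next
    r <- sqrt(mean(rowSums((xa - xb[p, , drop = FALSE])^2)))
    best <- min(best, r)
  }
  best
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
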