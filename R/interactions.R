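#' @include AllClasses.R chem-io.R
NULL

#' Geometric criteria for interaction detection
#'
#' All thresholds used by the detectors live in this one config object.
#' The defaults are community-standard values: hydrogen bonds use a
#' heavy-atom donor-acceptor distance cutoff with an optional D-H...A angle
#' test applied only when the donor hydrogen is explicit; alkyl hydrophobic
#' contacts use a carbon-carbon cutoff; pi-stacking uses ring-centroid
#' distance plus interplanar-angle bands for parallel and T-shaped
#' geometries.
#'
#' @param hbDistMax hydrogen-bond donor-acceptor distance cutoff, Angstrom.
#' @param hbAngleMin minimum D-H...A angle in degrees (explicit H only).
#' @param hpDistMax alkyl carbon-carbon contact cutoff, Angstrom.
#' @param piDistMax aromatic ring centroid-centroid cutoff, Angstrom.
#' @param piParallelMax maximum interplanar angle (degrees) for parallel
#'   stacking.
#' @param piTshapeMin,piTshapeMax interplanar angle band for T-shaped
#'   stacking.
#' @return a named list of class `interaction_criteria`.
#' @examples
#' crit <- interactionCriteria()
#' crit$hbDistMax
#' @export
interactionCriteria <- function(hbDistMax = 3.5, hbAngleMin = 120,
                                hpDistMax = 4.5, piDistMax = 5.5,
                                piParallelMax = 30, piTshapeMin = 60,
                                piTshapeMax = 90) {
  crit <- list(hbDistMax = hbDistMax, hbAngleMin = hbAngleMin,
               hpDistMax = hpDistMax, piDistMax = piDistMax,
               piParallelMax = piParallelMax, piTshapeMin = piTshapeMin,
               piTshapeMax = piTshapeMax)
  .assert(all(vapply(crit, function(v) is.numeric(v) && length(v) == 1 &&
                       is.finite(v) && v >= 0, logical(1))),
          "criteria must be single non-negative numbers")
  .assert(piTshapeMin <= piTshapeMax, "piTshapeMin must be <= piTshapeMax")
  structure(crit, class = "interaction_criteria")
}

#' Read interaction criteria from a JSON config file
#'
#' @param path JSON file with any subset of the [interactionCriteria()]
#'   arguments; unspecified values take the defaults.
#' @return an `interaction_criteria` object.
#' @export
readInteractionCriteria <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(interactionCriteria))
  .assert(all(names(cfg) %in% known), "unknown criteria field(s): ",
          paste(setdiff(names(cfg), known), collapse = ", "))
  do.call(interactionCriteria, cfg)
}

# ---- receptor typing ----

# Hydrogen-bond roles of protein N/O atoms, by residue and atom name.
# Backbone N donates, backbone O (and OXT) accepts; side chains follow the
# usual chemistry. Unknown N/O atoms fall back to "both" roles.
.receptor_hb_roles <- function(atoms) {
  roles <- character(nrow(atoms))
  is_no <- atoms$elem %in% c("N", "O")
  key <- paste(atoms$resname, atoms$atom)
  dict <- c(
    "SER OG" = "both", "THR OG1" = "both", "TYR OH" = "both",
    "ASN OD1" = "acceptor", "ASN ND2" = "donor",
    "GLN OE1" = "acceptor", "GLN NE2" = "donor",
    "ASP OD1" = "acceptor", "ASP OD2" = "acceptor",
    "GLU OE1" = "acceptor", "GLU OE2" = "acceptor",
    "LYS NZ" = "donor",
    "ARG NE" = "donor", "ARG NH1" = "donor", "ARG NH2" = "donor",
    "HIS ND1" = "both", "HIS NE2" = "both",
    "TRP NE1" = "donor")
  roles[is_no & atoms$atom == "N"] <- "donor"
  roles[is_no & atoms$atom %in% c("O", "OXT")] <- "acceptor"
  hit <- is_no & key %in% names(dict)
  roles[hit] <- dict[key[hit]]
  roles[is_no & roles == ""] <- "both"
  roles
}

# Ring atom names of aromatic side chains.
.aromatic_ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

# Receptor detection context: typed atoms and aromatic rings of the
# (binding-site-restricted) structure.
.receptor_context <- function(receptor) {
  at <- receptor@atoms
  bs <- receptor@bindingSite
  if (nrow(bs)) {
    keep <- paste(at$chain, at$resno) %in% paste(bs$chain, bs$resno)
    at <- at[keep, , drop = FALSE]
  }
  at$role <- .receptor_hb_roles(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  hyd <- which(at$elem == "H")
  rings <- list()
  ring_atoms <- integer()
  resk <- paste(at$chain, at$resno)
  for (rk in unique(resk[at$resname %in% names(.aromatic_ring_atoms)])) {
    sel <- resk == rk
    rn <- at$resname[sel][1]
    for (atoms_needed in .aromatic_ring_atoms[[rn]]) {
      idx <- which(sel & at$atom %in% atoms_needed)
      if (length(idx) == length(atoms_needed)) {
        rxyz <- xyz[idx, , drop = FALSE]
        ring_atoms <- c(ring_atoms, idx)
        rings[[length(rings) + 1L]] <- list(
          chain = at$chain[idx[1]], resno = at$resno[idx[1]],
          resname = rn, centroid = colMeans(rxyz),
          normal = .plane_normal(rxyz))
      }
    }
  }
  list(atoms = at, xyz = xyz, hydrogens = hyd, rings = rings,
       ring_atoms = unique(ring_atoms))
}

# ---- ligand typing ----

.standard_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                       F = 1, Cl = 1, Br = 1, I = 1, B = 3)

# Per-atom ligand typing from elements and bonding only: explicit and
# implicit hydrogen counts, donor/acceptor roles, apolar carbons.
.ligand_context <- function(mol) {
  n <- length(mol@elements)
  elem <- mol@elements
  b <- mol@bonds
  nbrs <- vector("list", n)
  bond_order_sum <- numeric(n)
  if (nrow(b)) {
    ord <- ifelse(b[, 3] == 4L, 1.5, b[, 3])
    for (i in seq_len(nrow(b))) {
      nbrs[[b[i, 1]]] <- c(nbrs[[b[i, 1]]], b[i, 2])
      nbrs[[b[i, 2]]] <- c(nbrs[[b[i, 2]]], b[i, 1])
      bond_order_sum[b[i, 1]] <- bond_order_sum[b[i, 1]] + ord[i]
      bond_order_sum[b[i, 2]] <- bond_order_sum[b[i, 2]] + ord[i]
    }
  }
  expl_h <- lapply(nbrs, function(v) v[elem[v] == "H"])
  val <- .standard_valence[elem]
  val <- ifelse(is.na(val), 0, val) + mol@charges * (elem == "N") -
    mol@charges * (elem == "O") * 0  # N+ gains a bond; O- handled below
  val[elem == "O" & mol@charges < 0] <- 1
  imp_h <- pmax(0, round(val - bond_order_sum))
  has_h <- lengths(expl_h) > 0 | (imp_h > 0 & lengths(expl_h) == 0 &
                                    !vapply(nbrs, function(v)
                                      any(elem[v] == "H"), logical(1)))
  is_no <- elem %in% c("N", "O")
  donor <- is_no & (lengths(expl_h) > 0 | (imp_h > 0))
  acceptor <- is_no & !(elem == "N" & mol@charges > 0)
  apolar_c <- elem == "C" &
    !vapply(nbrs, function(v) any(elem[v] %in% c("N", "O", "S")), logical(1))
  with_xyz <- !is.na(mol@coords[, 1])
  rings <- .aromatic_ligand_rings(mol)
  list(elem = elem, xyz = mol@coords, nbrs = nbrs, expl_h = expl_h,
       donor = donor & with_xyz, acceptor = acceptor & with_xyz,
       apolar_c = apolar_c & with_xyz, with_xyz = with_xyz,
       rings = rings,
       ring_atoms = unique(unlist(lapply(rings, `[[`, "atoms"))) %||%
         integer())
}

# Simple cycles of size 5-6 via per-edge shortest path in the graph minus
# that edge; a ring counts as aromatic when all its bonds are marked
# aromatic (order 4) or when its atoms are C/N, sp2-compatible (<= 3 heavy
# neighbours) and coplanar within 0.15 Angstrom.
.aromatic_ligand_rings <- function(mol, max_size = 6L) {
  b <- mol@bonds
  heavy_ok <- !is.na(mol@coords[, 1])
  if (!nrow(b)) return(list())
  n <- length(mol@elements)
  adj <- vector("list", n)
  for (i in seq_len(nrow(b))) {
    adj[[b[i, 1]]] <- c(adj[[b[i, 1]]], b[i, 2])
    adj[[b[i, 2]]] <- c(adj[[b[i, 2]]], b[i, 1])
  }
  bkey <- function(u, v) paste(pmin(u, v), pmax(u, v))
  border <- stats::setNames(b[, 3], bkey(b[, 1], b[, 2]))
  seen <- character()
  rings <- list()
  for (i in seq_len(nrow(b))) {
    u <- b[i, 1]; v <- b[i, 2]
    # BFS from u to v avoiding the direct edge
    prev <- rep(NA_integer_, n); prev[u] <- 0L
    queue <- u; depth <- stats::setNames(0L, u)
    dq <- c(u); dd <- c(0L); found <- FALSE
    while (length(dq) && !found) {
      cur <- dq[1]; cd <- dd[1]; dq <- dq[-1]; dd <- dd[-1]
      if (cd >= max_size - 1L) next
      for (w in adj[[cur]]) {
        if ((cur == u && w == v) || !is.na(prev[w])) next
        prev[w] <- cur
        if (w == v) { found <- TRUE; break }
        dq <- c(dq, w); dd <- c(dd, cd + 1L)
      }
    }
    if (!found) next
    path <- v
    while (path[1] != u) path <- c(prev[path[1]], path)
    if (length(path) < 5L || length(path) > max_size) next
    key <- paste(sort(path), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    ring_bonds <- vapply(seq_along(path), function(k)
      border[[bkey(path[k], path[k %% length(path) + 1L])]], numeric(1))
    elems <- mol@elements[path]
    n_heavy_nb <- vapply(path, function(a)
      sum(mol@elements[adj[[a]]] != "H"), numeric(1))
    aromatic <- all(ring_bonds == 4) ||
      (all(elems %in% c("C", "N")) && all(n_heavy_nb <= 3) &&
         all(heavy_ok[path]) && {
           xyz <- mol@coords[path, , drop = FALSE]
           nv <- .plane_normal(xyz)
           ctr <- colMeans(xyz)
           max(abs((xyz - rep(ctr, each = nrow(xyz))) %*% nv)) < 0.15
         })
    if (aromatic && all(heavy_ok[path])) {
      xyz <- mol@coords[path, , drop = FALSE]
      rings[[length(rings) + 1L]] <- list(
        atoms = path, centroid = colMeans(xyz), normal = .plane_normal(xyz))
    }
  }
  rings
}

.check_pose_coords <- function(pose) {
  .assert(is(pose, "PoseRecord"), "pose must be a PoseRecord")
  .assert(any(!is.na(pose@conformer@coords[, 1])),
          "pose conformer has no coordinates")
}

# Attached hydrogens of receptor donor atoms (receptors usually carry no
# explicit H; when they do, any H within 1.3 Angstrom of the donor is
# treated as bonded).
.receptor_attached_h <- function(ctx, donor_idx) {
  if (!length(ctx$hydrogens)) return(list())
  hxyz <- ctx$xyz[ctx$hydrogens, , drop = FALSE]
  lapply(donor_idx, function(i) {
    d <- .cross_dist(ctx$xyz[i, , drop = FALSE], hxyz)
    ctx$hydrogens[d[1, ] < 1.3]
  })
}

#' Detect hydrogen bonds between a receptor and a docked pose
#'
#' Returns every donor-acceptor pair whose heavy-atom distance is within
#' `hbDistMax`; when the donor hydrogen is explicit, the D-H...A angle must
#' also reach `hbAngleMin` (the test is skipped for implicit hydrogens).
#' Donor/acceptor typing uses elements and bonding only: ligand N/O atoms
#' donate when they carry an explicit or implicit hydrogen and accept unless
#' positively charged; receptor N/O roles come from a residue-atom
#' dictionary.
#'
#' @param receptor a [ReceptorStructure-class].
#' @param pose a [PoseRecord-class] with coordinates.
#' @param criteria an [interactionCriteria()] object.
#' @param context precomputed receptor context (internal optimization;
#'   leave `NULL`).
#' @return data.frame, one row per qualifying pair: chain, resno, resname,
#'   kind (`"HB"`), subtype (the ligand's role: `"donor"`/`"acceptor"`),
#'   distance, angle (`NA` when the angle test was skipped), lig_atom,
#'   rec_atom.
#' @export
detectHBonds <- function(receptor, pose, criteria = interactionCriteria(),
                         context = NULL) {
  .check_pose_coords(pose)
  ctx <- context %||% .receptor_context(receptor)
  lig <- .ligand_context(pose@conformer)
  rec_acc <- which(ctx$atoms$role %in% c("acceptor", "both"))
  rec_don <- which(ctx$atoms$role %in% c("donor", "both"))
  acc_li <- integer(); acc_ri <- integer()
  acc_d <- numeric(); acc_a <- numeric(); acc_role <- character()
  add_pairs <- function(lidx, ridx, lig_role, angle_fun) {
    if (!length(lidx) || !length(ridx)) return()
    d <- .cross_dist(lig$xyz[lidx, , drop = FALSE],
                     ctx$xyz[ridx, , drop = FALSE])
    hit <- which(d <= criteria$hbDistMax, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      li <- lidx[hit[k, 1]]; ri <- ridx[hit[k, 2]]
      ang <- angle_fun(li, ri)
      if (!is.na(ang) && ang < criteria$hbAngleMin) next
      acc_li <<- c(acc_li, li); acc_ri <<- c(acc_ri, ri)
      acc_d <<- c(acc_d, d[hit[k, 1], hit[k, 2]])
      acc_a <<- c(acc_a, ang); acc_role <<- c(acc_role, lig_role)
    }
  }
  # ligand donor -> receptor acceptor: angle at the ligand's explicit H
  add_pairs(which(lig$donor), rec_acc, "donor", function(li, ri) {
    hs <- lig$expl_h[[li]]
    hs <- hs[!is.na(lig$xyz[hs, 1])]
    if (!length(hs)) return(NA_real_)
    max(vapply(hs, function(h)
      .angle_deg(lig$xyz[li, ], lig$xyz[h, ], ctx$xyz[ri, ]), numeric(1)))
  })
  # ligand acceptor -> receptor donor: angle at the receptor's explicit H
  rec_h <- .receptor_attached_h(ctx, rec_don)
  add_pairs(which(lig$acceptor), rec_don, "acceptor", function(li, ri) {
    if (!length(rec_h)) return(NA_real_)
    hs <- rec_h[[match(ri, rec_don)]]
    if (is.null(hs) || !length(hs)) return(NA_real_)
    max(vapply(hs, function(h)
      .angle_deg(ctx$xyz[ri, ], ctx$xyz[h, ], lig$xyz[li, ]), numeric(1)))
  })
  if (!length(acc_ri)) {
    out <- .empty_interactions()
    out$lig_atom <- integer(); out$rec_atom <- integer()
    return(out)
  }
  data.frame(chain = ctx$atoms$chain[acc_ri],
             resno = ctx$atoms$resno[acc_ri],
             resname = ctx$atoms$resname[acc_ri], kind = "HB",
             subtype = acc_role, distance = acc_d, angle = acc_a,
             lig_atom = acc_li, rec_atom = acc_ri,
             stringsAsFactors = FALSE)
}

#' Detect hydrophobic contacts, typed alkyl / pi-stacking / mixed
#'
#' Alkyl contacts are pairs of an apolar ligand carbon (no N/O/S neighbour)
#' and a receptor side-chain carbon within `hpDistMax`; pairs where both
#' carbons belong to aromatic rings are excluded, since aromatic-aromatic
#' proximity is the stacking channel's business. Pi-stacking pairs
#' aromatic ring centroids within `piDistMax` whose interplanar angle falls
#' in the parallel band (<= `piParallelMax`) or the T-shaped band
#' (`piTshapeMin`-`piTshapeMax`). Contacts are reported per residue: a
#' residue contacted by both classes in the same pose appears once with
#' subtype `"mixed"`.
#'
#' @inheritParams detectHBonds
#' @return data.frame, one row per contacted residue: chain, resno,
#'   resname, kind (`"HP"`), subtype (`"alkyl"`, `"pi"` or `"mixed"`),
#'   distance (closest qualifying contact), angle (interplanar angle for
#'   pi, else `NA`).
#' @export
detectHydrophobic <- function(receptor, pose,
                              criteria = interactionCriteria(),
                              context = NULL) {
  .check_pose_coords(pose)
  ctx <- context %||% .receptor_context(receptor)
  lig <- .ligand_context(pose@conformer)
  v_chain <- character(); v_resno <- integer(); v_resname <- character()
  v_sub <- character(); v_d <- numeric(); v_a <- numeric()
  # alkyl: apolar ligand carbon vs receptor side-chain carbon
  # (aromatic-vs-aromatic carbon pairs belong to the pi channel)
  lidx <- which(lig$apolar_c)
  ridx <- which(ctx$atoms$elem == "C" & !(ctx$atoms$atom %in% c("C", "CA")))
  if (length(lidx) && length(ridx)) {
    d <- .cross_dist(lig$xyz[lidx, , drop = FALSE],
                     ctx$xyz[ridx, , drop = FALSE])
    both_arom <- outer(lidx %in% lig$ring_atoms,
                       ridx %in% ctx$ring_atoms, "&")
    hit <- which(d <= criteria$hpDistMax & !both_arom, arr.ind = TRUE)
    if (nrow(hit)) {
      ri <- ridx[hit[, 2]]
      v_chain <- ctx$atoms$chain[ri]; v_resno <- ctx$atoms$resno[ri]
      v_resname <- ctx$atoms$resname[ri]
      v_sub <- rep("alkyl", length(ri)); v_d <- d[hit]
      v_a <- rep(NA_real_, length(ri))
    }
  }
  # pi-stacking: ligand aromatic ring vs receptor aromatic side-chain ring
  for (lr in lig$rings) for (rr in ctx$rings) {
    dc <- sqrt(sum((lr$centroid - rr$centroid)^2))
    if (dc > criteria$piDistMax) next
    ang <- acos(pmin(1, abs(sum(lr$normal * rr$normal)))) * 180 / pi
    if (ang <= criteria$piParallelMax ||
        (ang >= criteria$piTshapeMin && ang <= criteria$piTshapeMax)) {
      v_chain <- c(v_chain, rr$chain); v_resno <- c(v_resno, rr$resno)
      v_resname <- c(v_resname, rr$resname); v_sub <- c(v_sub, "pi")
      v_d <- c(v_d, dc); v_a <- c(v_a, ang)
    }
  }
  if (!length(v_resno)) return(.empty_interactions())
  # residue-level merge: alkyl + pi on one residue -> mixed
  key <- paste(v_chain, v_resno)
  grp <- match(key, unique(key))
  n <- max(grp)
  first <- match(seq_len(n), grp)
  merged_sub <- merged_d <- merged_a <- vector("numeric", n)
  merged_sub <- character(n); merged_a <- rep(NA_real_, n)
  for (g in seq_len(n)) {
    sel <- grp == g
    st <- unique(v_sub[sel])
    merged_sub[g] <- if (length(st) > 1) "mixed" else st
    merged_d[g] <- min(v_d[sel])
    if ("pi" %in% st) merged_a[g] <- min(v_a[sel & v_sub == "pi"])
  }
  .order_interactions(data.frame(
    chain = v_chain[first], resno = v_resno[first],
    resname = v_resname[first], kind = "HP", subtype = merged_sub,
    distance = merged_d, angle = merged_a, stringsAsFactors = FALSE))
}

#' Profile all interactions of one pose
#'
#' Union of [detectHBonds()] and [detectHydrophobic()] results, deduplicated
#' to one entry per (residue, kind) key and ordered deterministically by
#' chain, residue number and kind. Hydrogen bonds are merged per residue:
#' the closest contact's geometry is kept, and the subtype becomes `"both"`
#' when the ligand acts as donor and acceptor towards the same residue.
#'
#' @inheritParams detectHBonds
#' @return an [InteractionProfile-class].
#' @examples
#' pocket <- generatePocket(nResidues = 6, seed = 1)
#' pose <- plantPose(pocket, data.frame(resno = residues(pocket)$resno[1],
#'                                      kind = "HB"), seed = 2)
#' profilePose(pocket, pose)
#' @export
profilePose <- function(receptor, pose, criteria = interactionCriteria(),
                        context = NULL) {
  ctx <- context %||% .receptor_context(receptor)
  hb <- detectHBonds(receptor, pose, criteria, context = ctx)
  hp <- detectHydrophobic(receptor, pose, criteria, context = ctx)
  hbm <- NULL
  if (nrow(hb)) {
    key <- paste(hb$chain, hb$resno)
    grp <- match(key, unique(key))
    n <- max(grp)
    idx_best <- vapply(seq_len(n), function(g) {
      sel <- which(grp == g); sel[which.min(hb$distance[sel])]
    }, integer(1))
    roles <- vapply(seq_len(n), function(g) {
      r <- unique(hb$subtype[grp == g])
      if (length(r) > 1) "both" else r
    }, character(1))
    hbm <- data.frame(chain = hb$chain[idx_best],
                      resno = hb$resno[idx_best],
                      resname = hb$resname[idx_best], kind = "HB",
                      subtype = roles, distance = hb$distance[idx_best],
                      angle = hb$angle[idx_best], stringsAsFactors = FALSE)
  }
  df <- rbind(hbm, if (nrow(hp)) hp else NULL)
  if (is.null(df)) df <- .empty_interactions()
  new("InteractionProfile", compoundId = pose@compoundId,
      structureId = pose@structureId,
      interactions = .order_interactions(df))
}

#' Export interaction profiles as a tidy table
#'
#' @param profiles list of [InteractionProfile-class] objects.
#' @param path optional CSV output path.
#' @return data.frame with columns compound_id, structure_id, chain,
#'   resnum, resname, kind, subtype, distance, angle.
#' @export
profilesToTable <- function(profiles, path = NULL) {
  if (is(profiles, "InteractionProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    df <- p@interactions
    if (!nrow(df)) return(NULL)
    data.frame(compound_id = p@compoundId, structure_id = p@structureId,
               chain = df$chain, resnum = df$resno, resname = df$resname,
               kind = df$kind, subtype = df$subtype,
               distance = df$distance, angle = df$angle,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(compound_id = character(), structure_id = character(),
                      chain = character(), resnum = integer(),
                      resname = character(), kind = character(),
                      subtype = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
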