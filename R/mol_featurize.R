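# Molecular featurization from SMILES: perception of atom/bond attributes on
# top of the ChemmineR/OpenBabel parse, the 69-d atom and 6-d bond feature
# layouts, the directed molecular graph, and the 2656-d concatenated
# fingerprint [MACCS 167 | ECFP 1024 | AtomPair 1024 | ErG-style 441].

# ---- feature layout constants -------------------------------------------

# 43 common organic/drug elements + 1 "other" slot = 44.
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "Si", "Se", "Ge",
  "As", "Te", "Na", "K", "Li", "Ca", "Mg", "Al", "Zn", "Fe", "Cu", "Mn",
  "Co", "Ni", "Cr", "Mo", "V", "Ti", "Sn", "Sb", "Bi", "Pb", "Hg", "Cd",
  "Pd", "Pt", "Au", "Ag", "Ba", "Sr")

HYBRIDIZATIONS <- c("sp", "sp2", "sp3", "sp3d", "other")
BOND_TYPES <- c("single", "double", "triple", "aromatic")

#' Atom and bond feature layout
#'
#' The fixed 69-d atom layout is: atom-symbol one-hot (44, last slot =
#' "other"), hybridization one-hot (5), heavy-atom degree one-hot 0-5 (6),
#' total hydrogen count one-hot 0-4 (5), implicit valence one-hot 0-6 (7),
#' in-ring flag (1), aromatic flag (1). The 6-d bond layout is: bond-type
#' one-hot {single, double, triple, aromatic} (4), conjugated flag (1),
#' in-ring flag (1). Out-of-range degree/H/valence values clamp to the last
#' slot.
#'
#' @return list describing block names and widths of both layouts.
#' @export
feature_layout <- function() {
  list(atom = c(symbol = 44L, hybridization = 5L, degree = 6L,
                total_h = 5L, implicit_valence = 7L, in_ring = 1L,
                aromatic = 1L),
       bond = c(bond_type = 4L, conjugated = 1L, in_ring = 1L))
}

# ---- SMILES parsing and perception --------------------------------------

parse_error <- function(smiles, why = "cannot be parsed") {
  stop(structure(class = c("capsddi_parse_error", "error", "condition"),
                 list(message = paste0("SMILES '", smiles, "' ", why),
                      call = sys.call(-1), smiles = smiles)))
}

# MDL charge codes -> formal charge.
.mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Smallest admissible valence >= bond-order sum, per element.
element_valence <- function(element, charge, order_sum) {
  pick <- function(opts) {
    ok <- opts[opts >= order_sum]
    if (length(ok)) min(ok) else order_sum
  }
  switch(element,
    C = max(0L, 4L - abs(charge)),
    N = , P = {
      base <- if (element == "N") 3L + charge else pick(c(3L, 5L) + charge)
      max(base, 0L)
    },
    O = max(0L, 2L + charge),
    S = , Se = pick(c(2L, 4L, 6L) + charge),
    F = , Cl = , Br = , I = if (charge == 0L) 1L else 0L,
    B = 3L,
    Si = 4L,
    order_sum)  # unknown elements carry no implicit hydrogens
}

#' Parse a SMILES string into an annotated molecule
#'
#' Parses through ChemmineR/OpenBabel and derives per-atom and per-bond
#' attributes: element, formal charge, heavy-atom degree, implicit/total
#' hydrogens, hybridization, ring membership, aromaticity and bond
#' conjugation. Hydrogens are implicit: the molecule is the heavy-atom graph.
#'
#' @param smiles a SMILES string.
#' @return list of class `capsddi_mol` with data.frames `atoms` and `bonds`.
#' @export
parse_molecule <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    parse_error(as.character(smiles)[1] %||% "NA", "is not a valid string")
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) parse_error(smiles))
  sdf <- tryCatch(sdfset[[1]], error = function(e) parse_error(smiles))
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) parse_error(smiles, "yields no atoms")
  if (!any(grepl("_", rownames(ab)))) {
    # ChemmineR mis-parses bond-less molecules; recover atoms from raw molfile
    raw <- tryCatch(ChemmineOB::convertFormat("SMILES", "SDF", smiles),
                    error = function(e) parse_error(smiles))
    lines <- strsplit(raw, "\n")[[1]] %||% character(0)
    if (length(lines) < 5) parse_error(smiles)
    natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
    if (is.na(natoms) || natoms < 1) parse_error(smiles, "yields no atoms")
    element <- vapply(lines[4 + seq_len(natoms)], function(l) {
      trimws(substr(l, 32, 34))
    }, "", USE.NAMES = FALSE)
    charge <- integer(natoms)
  } else {
    element <- sub("_.*$", "", rownames(ab))
    charge_code <- if ("C6" %in% colnames(ab)) as.character(ab[, "C6"]) else
      rep("0", nrow(ab))
    charge <- .mdl_charge[charge_code]
    charge[is.na(charge)] <- 0L
  }
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || length(bb) == 0 || !is.matrix(bb) || nrow(bb) == 0 ||
      !all(c("C1", "C2", "C3") %in% colnames(bb))) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bb <- matrix(as.integer(bb), ncol = ncol(bb),
                 dimnames = list(NULL, colnames(bb)))
    bonds <- data.frame(i = bb[, "C1"], j = bb[, "C2"], order = bb[, "C3"])
  }
  # strip explicit hydrogens into neighbor H counts
  n_all <- length(element)
  explicit_h <- integer(n_all)
  is_h <- element == "H"
  if (any(is_h)) {
    for (k in seq_len(nrow(bonds))) {
      if (is_h[bonds$i[k]]) explicit_h[bonds$j[k]] <- explicit_h[bonds$j[k]] + 1L
      if (is_h[bonds$j[k]]) explicit_h[bonds$i[k]] <- explicit_h[bonds$i[k]] + 1L
    }
    keep <- which(!is_h)
    remap <- match(seq_len(n_all), keep)
    bonds <- bonds[!is_h[bonds$i] & !is_h[bonds$j], , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    element <- element[keep]; charge <- charge[keep]
    explicit_h <- explicit_h[keep]
    rownames(ab) <- NULL
  }
  n <- length(element)
  if (n == 0) parse_error(smiles, "has no heavy atoms")

  # ring and aromaticity perception
  atom_ring <- logical(n); atom_arom <- logical(n)
  bond_ring <- logical(nrow(bonds)); bond_arom <- logical(nrow(bonds))
  if (nrow(bonds) >= 3) {
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS)) {
      atom_of <- function(lbl) as.integer(sub("^.*_", "", lbl))
      bkey <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
      for (ri in seq_along(rr$RINGS)) {
        ids <- atom_of(rr$RINGS[[ri]])
        atom_ring[ids] <- TRUE
        arom <- isTRUE(rr$AROMATIC[[ri]])
        if (arom) atom_arom[ids] <- TRUE
        cyc <- cbind(ids, c(ids[-1], ids[1]))
        rkey <- paste(pmin(cyc[, 1], cyc[, 2]), pmax(cyc[, 1], cyc[, 2]))
        hit <- bkey %in% rkey
        bond_ring[hit] <- TRUE
        if (arom) bond_arom[hit] <- TRUE
      }
    }
  }

  degree <- integer(n); order_sum <- integer(n); n_double <- integer(n)
  n_triple <- integer(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      for (a in c(bonds$i[k], bonds$j[k])) {
        degree[a] <- degree[a] + 1L
        order_sum[a] <- order_sum[a] + bonds$order[k]
        if (bonds$order[k] == 2L) n_double[a] <- n_double[a] + 1L
        if (bonds$order[k] == 3L) n_triple[a] <- n_triple[a] + 1L
      }
    }
  }
  implicit_h <- vapply(seq_len(n), function(a) {
    v <- element_valence(element[a], charge[a], order_sum[a])
    max(0L, as.integer(v) - order_sum[a] - explicit_h[a])
  }, integer(1))
  hybrid <- ifelse(n_triple > 0 | n_double >= 2, "sp",
                   ifelse(atom_arom | n_double == 1, "sp2", "sp3"))
  sp2ish <- hybrid %in% c("sp", "sp2")
  conjugated <- if (nrow(bonds)) sp2ish[bonds$i] & sp2ish[bonds$j] else logical(0)

  structure(list(
    smiles = smiles,
    atoms = data.frame(element = element, charge = as.integer(charge),
                       degree = degree, implicit_h = implicit_h,
                       total_h = implicit_h + explicit_h,
                       hybridization = hybrid, in_ring = atom_ring,
                       aromatic = atom_arom, stringsAsFactors = FALSE),
    bonds = data.frame(i = bonds$i, j = bonds$j, order = bonds$order,
                       aromatic = bond_arom, conjugated = conjugated,
                       in_ring = bond_ring)),
    class = "capsddi_mol")
}

#' 69-dimensional atom feature vector
#'
#' See [feature_layout()] for the fixed block layout. Out-of-vocabulary
#' elements map to the final "other" symbol slot; out-of-range counts clamp
#' to the final slot of their block.
#'
#' @param mol a [parse_molecule()] result.
#' @param idx atom index.
#' @return Numeric vector of length 69.
#' @export
atom_feature <- function(mol, idx) {
  a <- mol$atoms[idx, ]
  c(one_hot(a$element, ATOM_SYMBOLS, other = TRUE),
    one_hot(a$hybridization, HYBRIDIZATIONS),
    one_hot(min(a$degree, 5L), 0:5),
    one_hot(min(a$total_h, 4L), 0:4),
    one_hot(min(a$implicit_h, 6L), 0:6),
    as.numeric(a$in_ring),
    as.numeric(a$aromatic))
}

#' 6-dimensional bond feature vector
#'
#' Bond-type one-hot (single/double/triple/aromatic) + conjugated flag +
#' in-ring flag.
#'
#' @param mol a [parse_molecule()] result.
#' @param idx bond index (row of `mol$bonds`).
#' @return Numeric vector of length 6.
#' @export
bond_feature <- function(mol, idx) {
  b <- mol$bonds[idx, ]
  type <- if (b$aromatic) "aromatic" else
    c("single", "double", "triple")[min(b$order, 3L)]
  c(one_hot(type, BOND_TYPES), as.numeric(b$conjugated), as.numeric(b$in_ring))
}

#' Build the directed molecular graph of a drug
#'
#' Nodes are heavy atoms with 69-d features; every chemical bond contributes
#' two directed edges carrying the same 6-d feature vector.
#'
#' @param smiles a SMILES string.
#' @return list of class `molecular_graph` with `atom_features`
#'   (n_atoms x 69), `edges` (n_directed_edges x 2, columns src/dst) and
#'   `edge_features` (n_directed_edges x 6).
#' @export
build_molecular_graph <- function(smiles) {
  mol <- parse_molecule(smiles)
  n <- nrow(mol$atoms)
  af <- t(vapply(seq_len(n), function(i) atom_feature(mol, i), numeric(69)))
  nb <- nrow(mol$bonds)
  if (nb) {
    bf <- t(vapply(seq_len(nb), function(i) bond_feature(mol, i), numeric(6)))
    edges <- cbind(src = c(mol$bonds$i, mol$bonds$j),
                   dst = c(mol$bonds$j, mol$bonds$i))
    ef <- rbind(bf, bf)
  } else {
    edges <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("src", "dst")))
    ef <- matrix(numeric(0), ncol = 6)
  }
  structure(list(atom_features = af, edges = edges, edge_features = ef,
                 smiles = smiles),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", nrow(x$atom_features), " atoms, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

# ---- fingerprints --------------------------------------------------------

# XOR-fold a nonnegative descriptor (< 2^53) into 10 bits; the atom-pair
# descriptor packs pair type in high bits and distance in low bits, so a
# plain modulus would collide almost everything.
fold_hash_1024 <- function(x) {
  x <- as.numeric(x)
  h <- rep(0L, length(x))
  for (k in 0:5) {
    h <- bitwXor(h, as.integer(x %% 1024))
    x <- x %/% 1024
  }
  h
}

.fp_env <- new.env(parent = emptyenv())

ob_fingerprint_bits <- function(obmol, name) {
  handle <- .fp_env[[name]]
  if (is.null(handle)) {
    handle <- ChemmineOB:::OBFingerprint_FindFingerprint(name)
    if (ChemmineOB:::isNullPtr(handle)) stop("OpenBabel fingerprint '", name,
                                             "' unavailable")
    .fp_env[[name]] <- handle
  }
  words <- ChemmineOB:::OBFingerprint_GetFingerprint(handle, obmol,
                                                     numeric(1))[[2]]
  # little-endian bit unpack matches OBFingerprint_GetBit's i>>5 / i&31 layout
  as.integer(intToBits(words))
}

ob_molecule <- function(smiles) {
  res <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                  error = function(e) NULL)
  if (is.null(res) || !length(res)) parse_error(smiles)
  res[[1]]
}

#' ErG-style reduced-graph pharmacophore fingerprint
#'
#' Atoms are assigned pharmacophore types (H-bond donor, H-bond acceptor,
#' positive, negative, hydrophobic, aromatic); each typed atom pair at
#' topological distance 1..21 increments the corresponding (type-pair,
#' distance) cell by 1, with fuzzy increments of 0.3 on the two neighbouring
#' distance bins, following the ErG scheme. 21 unordered type pairs x 21
#' distance bins = 441 nonnegative values.
#'
#' @param mol a [parse_molecule()] result.
#' @param max_dist largest path length encoded (default 21).
#' @return Numeric vector of length 441.
#' @export
erg_fingerprint <- function(mol, max_dist = 21L) {
  types <- c("donor", "acceptor", "positive", "negative", "hydrophobic",
             "aromatic")
  nt <- length(types)
  pair_idx <- matrix(0L, nt, nt)
  k <- 0L
  for (a in seq_len(nt)) for (b in a:nt) {
    k <- k + 1L
    pair_idx[a, b] <- k; pair_idx[b, a] <- k
  }
  v <- numeric(k * max_dist)        # 21 * 21 = 441
  at <- mol$atoms
  n <- nrow(at)
  atom_types <- lapply(seq_len(n), function(i) {
    e <- at$element[i]
    out <- integer(0)
    if (e %in% c("N", "O") && at$total_h[i] >= 1L) out <- c(out, 1L)
    if (e %in% c("N", "O") && at$charge[i] <= 0L) out <- c(out, 2L)
    if (at$charge[i] > 0L) out <- c(out, 3L)
    if (at$charge[i] < 0L) out <- c(out, 4L)
    if (e %in% c("C", "S", "F", "Cl", "Br", "I") && !at$aromatic[i]) {
      nb <- unique(c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i]))
      if (!any(at$element[nb] %in% c("N", "O", "P"))) out <- c(out, 5L)
    }
    if (at$aromatic[i]) out <- c(out, 6L)
    out
  })
  if (n >= 2 && nrow(mol$bonds)) {
    g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    d <- igraph::distances(g)
    for (a in seq_len(n - 1)) {
      ta <- atom_types[[a]]
      if (!length(ta)) next
      for (b in (a + 1):n) {
        tb <- atom_types[[b]]
        if (!length(tb)) next
        dist <- d[a, b]
        if (!is.finite(dist) || dist < 1 || dist > max_dist) next
        for (x in ta) for (y in tb) {
          p <- pair_idx[x, y]
          base <- (p - 1L) * max_dist
          v[base + dist] <- v[base + dist] + 1
          if (dist > 1) v[base + dist - 1] <- v[base + dist - 1] + 0.3
          if (dist < max_dist) v[base + dist + 1] <- v[base + dist + 1] + 0.3
        }
      }
    }
  }
  v
}

#' Concatenated molecular fingerprint of a drug
#'
#' Computes the MACCS key fingerprint (167 slots), the circular ECFP
#' fingerprint of diameter 4 folded to 1024 bits, the topological atom-pair
#' fingerprint hashed to 1024 bits, and the 441-value ErG-style pharmacophore
#' fingerprint ([erg_fingerprint()]), concatenated in that fixed order to a
#' 2656-d vector. MACCS and ECFP come from OpenBabel, atom pairs from
#' ChemmineR; molecules with fewer than two heavy atoms have an all-zero
#' atom-pair block.
#'
#' @param smiles a SMILES string.
#' @return list of class `fingerprint_vector` with `values` (length 2656) and
#'   `blocks` (named index list).
#' @export
compute_fingerprints <- function(smiles) {
  mol <- parse_molecule(smiles)           # validates; typed error if bad
  obmol <- ob_molecule(smiles)
  maccs <- ob_fingerprint_bits(obmol, "MACCS")[1:167]
  ecfp_raw <- ob_fingerprint_bits(obmol, "ECFP4")
  ecfp <- numeric(1024)
  on <- which(ecfp_raw == 1L) - 1L
  ecfp[unique(on %% 1024L) + 1L] <- 1
  apfp <- numeric(1024)
  if (nrow(mol$atoms) >= 2 && nrow(mol$bonds) >= 1) {
    sdfset <- suppressWarnings(ChemmineR::smiles2sdf(c(m = smiles)))
    apset <- suppressWarnings(ChemmineR::sdf2ap(sdfset))
    desc <- ChemmineR::ap(apset[[1]])
    if (is.numeric(desc) && length(desc)) {
      apfp[unique(fold_hash_1024(desc)) + 1L] <- 1
    }
  }
  erg <- erg_fingerprint(mol)
  values <- c(maccs, ecfp, apfp, erg)
  structure(list(values = values,
                 blocks = list(maccs = 1:167, ecfp = 168:1191,
                               atompair = 1192:2215, erg = 2216:2656)),
            class = "fingerprint_vector")
}

#' Concatenate two drugs' feature vectors into a pair feature
#'
#' @param feat_i,feat_j equal-length numeric vectors for the two drugs.
#' @return `c(feat_i, feat_j)`.
#' @export
pair_concat <- function(feat_i, feat_j) {
  if (length(feat_i) != length(feat_j)) {
    stop("per-drug feature widths differ: ", length(feat_i), " vs ",
         length(feat_j))
  }
  c(feat_i, feat_j)
}

#' Binary pharmacology vector of a drug
#'
#' Concatenation of the enzyme-annotation and target-annotation bit blocks
#' (344 + 1815 = 2159 at full scale; widths are configurable).
#'
#' @param enzyme_bits,target_bits binary vectors.
#' @return Numeric 0/1 vector of length `length(enzyme_bits) + length(target_bits)`.
#' @export
pharm_vector <- function(enzyme_bits, target_bits) {
  v <- c(enzyme_bits, target_bits)
  if (!all(v %in% c(0, 1))) stop("pharmacology vectors must be binary")
  as.numeric(v)
}
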