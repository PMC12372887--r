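#' Read a protein structure (PDB or mmCIF)
#'
#' Parses coordinates into a flat atom table. Hydrogens are dropped,
#' alternate locations are resolved to the highest-occupancy conformer (ties
#' prefer altloc `A`), and heteroatoms are retained but flagged so they are
#' excluded from protein residue indexing.
#'
#' @param file Path (or URL) to a `.pdb` or `.cif`/`.mmcif` file.
#' @param model_index 1-based model number for multi-model files.
#' @return `data.frame` of class `structure_model` with columns `chain`,
#'   `resno`, `ins`, `resid`, `elety` (atom name), `element`, `x`, `y`, `z`,
#'   `o` (occupancy), `alt`, `is_het`; attribute `structure_id`.
#' @export
read_structure <- function(file, model_index = 1) {
  is_cif <- grepl("\\.(cif|mmcif)(\\.gz)?$", file, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(file, multi = model_index > 1)
      else bio3d::read.pdb(file, multi = model_index > 1)),
    error = function(e) stop("could not parse structure file '", file,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("structure '", file, "' contains no atoms")
  if (model_index > 1) {
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || model_index > nmod) {
      stop("model ", model_index, " not present in '", file, "'")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  element <- toupper(trimws(if (!is.null(at$elesy)) at$elesy else ""))
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1))
  element[!nzchar(element) | is.na(element)] <-
    guess[!nzchar(element) | is.na(element)]
  model <- data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    is_het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  model <- model[model$element != "H" & model$element != "D", , drop = FALSE]
  model <- resolve_altloc(model)
  if (any(!is.finite(c(model$x, model$y, model$z)))) {
    stop("non-finite coordinates in '", file, "'")
  }
  rownames(model) <- NULL
  attr(model, "structure_id") <-
    sub("\\.(pdb|cif|mmcif)(\\.gz)?$", "", basename(file), ignore.case = TRUE)
  class(model) <- c("structure_model", "data.frame")
  model
}

# Keep one conformer per atom: highest occupancy, ties resolved toward
# altloc 'A', then file order.
resolve_altloc <- function(model) {
  key <- paste(model$chain, model$resno, model$ins, model$resid, model$elety,
               sep = "\r")
  if (!anyDuplicated(key)) return(model)
  pref <- order(key, -model$o, model$alt != "A", seq_len(nrow(model)))
  keep <- pref[!duplicated(key[pref])]
  model[sort(keep), , drop = FALSE]
}

#' Construct a structure model from an atom table
#'
#' Used by the synthetic generators; validates the column set and coordinate
#' finiteness.
#'
#' @param atoms `data.frame` with at least `chain`, `resno`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`.
#' @param structure_id Identifier stored with the model.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, structure_id = "model") {
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atom table lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$is_het)) atoms$is_het <- FALSE
  stopifnot(all(is.finite(c(atoms$x, atoms$y, atoms$z))))
  atoms <- atoms[, c(need[1:2], "ins", need[3:8], "o", "alt", "is_het")]
  rownames(atoms) <- NULL
  attr(atoms, "structure_id") <- structure_id
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Write a structure model as PDB
#'
#' @param model A `structure_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(model, file) {
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   resno = model$resno, resid = model$resid,
                   eleno = seq_len(nrow(model)), elety = model$elety,
                   chain = model$chain, o = model$o, b = rep(0, nrow(model)),
                   elesy = model$element)
  invisible(file)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure %s: %d atoms, %d residues, chains: %s\n",
              attr(x, "structure_id"), nrow(x),
              length(unique(paste(x$chain, x$resno, x$ins)[!x$is_het])),
              paste(unique(x$chain), collapse = ", ")))
  invisible(x)
}

# xyz of one named atom; errors name the residue and atom when absent
get_atom <- function(model, chain, resno, elety) {
  i <- which(model$chain == chain & model$resno == resno &
             model$elety == elety)
  if (length(i) == 0) {
    stop("missing atom ", elety, " in residue ", resno, " chain ", chain)
  }
  as.numeric(model[i[1], c("x", "y", "z")])
}

#' Euclidean distance between two named atoms
#'
#' Computation keeps full precision; round only for reporting (tables print
#' one decimal).
#'
#' @param model A `structure_model`.
#' @param a,b Atom selectors: `list(chain=, resno=, elety=)` (or unnamed
#'   `list(chain, resno, atom-name)`).
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(model, a, b) {
  sel <- function(s) {
    if (is.null(names(s)) || !all(c("chain", "resno", "elety") %in% names(s)))
      s <- stats::setNames(s, c("chain", "resno", "elety"))
    get_atom(model, as.character(s[["chain"]]), as.numeric(s[["resno"]]),
             as.character(s[["elety"]]))
  }
  sqrt(sum((sel(a) - sel(b))^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle defined by four points
#'
#' Standard IUPAC sign convention; result in degrees in the half-open range
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric xyz triples.
#' @return Angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone Phi/Psi dihedrals over a residue range
#'
#' IUPAC convention: `Phi(i) = C(i-1)-N(i)-CA(i)-C(i)` and
#' `Psi(i) = N(i)-CA(i)-C(i)-N(i+1)`. Angles are reported in degrees in
#' (-180, 180]; dihedrals undefined at chain termini, or spanning a chain
#' break (peptide C-N distance above `break_cutoff`), are `NA` (a warning is
#' emitted for breaks).
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param resnos Integer vector of author residue numbers to report.
#' @param break_cutoff Peptide-bond C-N distance (Angstrom) above which the
#'   chain is considered broken (default 2.5).
#' @return `data.frame` with `residue_number`, `resid`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(model, chain, resnos, break_cutoff = 2.5) {
  prot <- model[!model$is_het & model$chain == chain, , drop = FALSE]
  all_res <- sort(unique(prot$resno))
  bb <- function(resno, elety) {
    i <- which(prot$resno == resno & prot$elety == elety)
    if (length(i) == 0) return(NULL)
    as.numeric(prot[i[1], c("x", "y", "z")])
  }
  bonded <- function(r1, r2) {
    # consecutive author numbers linked by a real peptide bond
    c1 <- bb(r1, "C"); n2 <- bb(r2, "N")
    if (is.null(c1) || is.null(n2)) return(FALSE)
    d <- sqrt(sum((c1 - n2)^2))
    if (d > break_cutoff) {
      warning("chain break between residues ", r1, " and ", r2,
              sprintf(" (C-N %.2f A)", d))
      return(FALSE)
    }
    TRUE
  }
  rows <- lapply(resnos, function(r) {
    res_name <- prot$resid[prot$resno == r][1]
    n <- bb(r, "N"); ca <- bb(r, "CA"); cc <- bb(r, "C")
    phi <- psi <- NA_real_
    if (!is.null(n) && !is.null(ca) && !is.null(cc)) {
      prev <- if ((r - 1) %in% all_res) r - 1 else NA
      nxt  <- if ((r + 1) %in% all_res) r + 1 else NA
      if (!is.na(prev) && bonded(prev, r)) {
        cp <- bb(prev, "C")
        if (!is.null(cp)) phi <- torsion_angle(cp, n, ca, cc)
      }
      if (!is.na(nxt) && bonded(r, nxt)) {
        nn <- bb(nxt, "N")
        if (!is.null(nn)) psi <- torsion_angle(n, ca, cc, nn)
      }
    }
    data.frame(residue_number = r,
               resid = if (is.na(res_name)) "" else res_name,
               phi = phi, psi = psi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect disulfide bridges
#'
#' Reports unordered cysteine pairs whose SG-SG distance is at or below
#' `max_sg_distance` (a typical S-S bond is about 2.05 Angstrom). Pairs are
#' matched greedily nearest-first so each cysteine appears in at most one
#' pair. Cysteines lacking an SG atom are skipped with a warning.
#'
#' @param model A `structure_model`.
#' @param max_sg_distance Distance cutoff in Angstrom (default 2.3).
#' @return `data.frame` with `chain1`, `resno1`, `chain2`, `resno2`,
#'   `sg_distance`, sorted by distance.
#' @export
detect_disulfides <- function(model, max_sg_distance = 2.3) {
  cys <- model[!model$is_het & model$resid == "CYS", , drop = FALSE]
  res <- unique(cys[, c("chain", "resno")])
  empty <- data.frame(chain1 = character(0), resno1 = numeric(0),
                      chain2 = character(0), resno2 = numeric(0),
                      sg_distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(res) < 2) return(empty)
  sg <- lapply(seq_len(nrow(res)), function(i) {
    s <- cys[cys$chain == res$chain[i] & cys$resno == res$resno[i] &
             cys$elety == "SG", , drop = FALSE]
    if (nrow(s) == 0) {
      warning("cysteine ", res$resno[i], " chain ", res$chain[i],
              " lacks an SG atom; skipped")
      return(NULL)
    }
    as.numeric(s[1, c("x", "y", "z")])
  })
  ok <- !vapply(sg, is.null, logical(1))
  res <- res[ok, , drop = FALSE]; sg <- sg[ok]
  n <- nrow(res)
  if (n < 2) return(empty)
  cand <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((sg[[i]] - sg[[j]])^2))
    if (d <= max_sg_distance) {
      cand <- rbind(cand, data.frame(i = i, j = j, d = d))
    }
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$d), , drop = FALSE]
  used <- logical(n); keep <- NULL
  for (k in seq_len(nrow(cand))) {
    if (!used[cand$i[k]] && !used[cand$j[k]]) {
      used[cand$i[k]] <- used[cand$j[k]] <- TRUE
      keep <- rbind(keep, cand[k, ])
    }
  }
  out <- data.frame(chain1 = res$chain[keep$i], resno1 = res$resno[keep$i],
                    chain2 = res$chain[keep$j], resno2 = res$resno[keep$j],
                    sg_distance = keep$d, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Regulatory-spine contact assessment
#'
#' For each consecutive pair along the ordered spine residues, computes the
#' minimum distance over side-chain heavy atoms. The spine is `"broken"` when
#' any adjacent pair exceeds `contact_cutoff`; the breaking link(s) are
#' identified. A spine residue with no resolved side-chain atoms breaks its
#' links (with a warning).
#'
#' @param model A `structure_model`.
#' @param spine_residues Ordered integer vector of spine residue numbers
#'   (at least 2).
#' @param chain Chain identifier (default `"A"`).
#' @param contact_cutoff Contact distance in Angstrom (default 4.5).
#' @return List with `status` (`"intact"` or `"broken"`), `pairs`
#'   (`data.frame` of `res1`, `res2`, `min_distance`, `in_contact`), and
#'   `breaking` (residue pairs exceeding the cutoff).
#' @export
spine_contacts <- function(model, spine_residues, chain = "A",
                           contact_cutoff = 4.5) {
  if (length(spine_residues) < 2) stop("need at least 2 spine residues")
  backbone <- c("N", "CA", "C", "O", "OXT")
  side <- function(r) {
    s <- model[!model$is_het & model$chain == chain & model$resno == r &
               !(model$elety %in% backbone), , drop = FALSE]
    if (nrow(s) == 0) {
      warning("spine residue ", r, " has no side-chain heavy atoms")
      return(NULL)
    }
    as.matrix(s[, c("x", "y", "z")])
  }
  sc <- lapply(spine_residues, side)
  pairs <- data.frame(res1 = spine_residues[-length(spine_residues)],
                      res2 = spine_residues[-1], min_distance = NA_real_)
  for (k in seq_len(nrow(pairs))) {
    a <- sc[[k]]; b <- sc[[k + 1]]
    pairs$min_distance[k] <- if (is.null(a) || is.null(b)) Inf else {
      min(apply(a, 1, function(p) {
        sqrt(colSums((t(b) - p)^2))
      }))
    }
  }
  pairs$in_contact <- pairs$min_distance <= contact_cutoff
  list(status = if (all(pairs$in_contact)) "intact" else "broken",
       pairs = pairs,
       breaking = pairs[!pairs$in_contact, c("res1", "res2"), drop = FALSE])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets. The returned rotation is orthogonal with
#' determinant +1 (reflections are excluded).
#'
#' @param mobile,target Numeric n x 3 coordinate matrices with matched rows
#'   (n >= 3, not collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom, after transform). Transform a point set with
#'   [apply_transform()].
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3) {
    stop("mobile and target must be matched n x 3 matrices")
  }
  if (nrow(mobile) < 3) stop("need at least 3 paired atoms")
  cm <- colMeans(mobile); ct <- colMeans(target)
  m0 <- sweep(mobile, 2, cm); t0 <- sweep(target, 2, ct)
  if (min(svd(m0)$d) < 1e-8 * max(svd(m0)$d, 1)) {
    stop("degenerate (collinear) atom set")
  }
  h <- t(m0) %*% t0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- ct - as.numeric(rot %*% cm)
  fitted <- apply_transform(mobile, rot, trans)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 vector.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, "+")
}

#' Apply a rigid transform to a structure model
#'
#' @param model A `structure_model`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 vector.
#' @return The transformed model.
#' @export
transform_model <- function(model, rotation, translation) {
  xyz <- apply_transform(as.matrix(model[, c("x", "y", "z")]),
                         rotation, translation)
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Extract coordinates of selected atoms
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier (default all).
#' @param resno Residue numbers (default all).
#' @param elety Atom names, e.g. `"CA"` (default all).
#' @return n x 3 numeric matrix in model order.
#' @export
atom_coords <- function(model, chain = NULL, resno = NULL, elety = NULL) {
  keep <- !model$is_het
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(elety)) keep <- keep & model$elety %in% elety
  as.matrix(model[keep, c("x", "y", "z")])
}
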