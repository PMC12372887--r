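with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Synthetic kinome panel with known group membership
#'
#' Draws remaining activities so the planted inhibited kinases fall at or
#' below the inhibited cutoff, planted non-inhibited kinases at or above the
#' non-inhibited cutoff, and the remainder strictly between. Fully
#' deterministic under `seed`.
#'
#' @param n_inhibited,n_noninhibited,n_between Planted group sizes.
#' @param compound_id Compound label for every record.
#' @param inhibited_cutoff,noninhibited_cutoff Percent cutoffs (defaults
#'   50 / 99).
#' @param seed Integer seed (required).
#' @return List with `table` (a `panel_table`) and `truth` (`data.frame`
#'   with `kinase_id`, `group`).
#' @export
make_panel <- function(n_inhibited = 7, n_noninhibited = 10,
                       n_between = 123, compound_id = "CMPD-1",
                       inhibited_cutoff = 50, noninhibited_cutoff = 99,
                       seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  n <- n_inhibited + n_noninhibited + n_between
  if (n == 0) {
    return(list(table = empty_panel_table(),
                truth = data.frame(kinase_id = character(0),
                                   group = character(0))))
  }
  with_seed(seed, {
    ids <- sprintf("K%03d", seq_len(n))
    group <- c(rep("inhibited", n_inhibited),
               rep("noninhibited", n_noninhibited),
               rep("unclassified", n_between))
    act <- numeric(n)
    act[group == "inhibited"] <- stats::runif(n_inhibited, 0,
                                              inhibited_cutoff)
    act[group == "noninhibited"] <- stats::runif(n_noninhibited,
                                                 noninhibited_cutoff, 110)
    gap <- noninhibited_cutoff - inhibited_cutoff
    act[group == "unclassified"] <- stats::runif(
      n_between, inhibited_cutoff + 0.01 * gap,
      noninhibited_cutoff - 0.01 * gap)
    perm <- sample.int(n)
    tab <- data.frame(kinase_id = ids[perm], compound_id = compound_id,
                      remaining_activity = act[perm], sem = NA_real_,
                      n_replicates = 1L, stringsAsFactors = FALSE)
    class(tab) <- c("panel_table", "data.frame")
    list(table = tab,
         truth = data.frame(kinase_id = ids, group = group,
                            stringsAsFactors = FALSE))
  })
}

#' Synthetic alignment with planted per-column conservation
#'
#' Emits three kinds of columns: *conserved* (a single residue in every
#' sequence), *variable* (each sequence samples uniformly from a 10-residue
#' pool), and *intermediate* (a dominant residue at a per-column fraction
#' between 0.55 and 0.9, remainder from the pool). Intermediate columns fill
#' the middle of the score distribution so rank-binned grades push planted
#' conserved columns into the top grades and planted variable columns into
#' the bottom ones. Per-column gap fractions are controllable.
#'
#' @param n_seqs Number of sequences (>= 2; default 50).
#' @param n_conserved,n_variable,n_intermediate Column counts per kind
#'   (defaults 20 / 20 / 50).
#' @param gap_fraction Scalar or per-column vector of gap fractions in
#'   \[0, 1\] (default 0).
#' @param seed Integer seed (required).
#' @return List with `msa` (`kinase_msa`), `labels` (per-column kind), and
#'   `dominant` (the planted residue for conserved/intermediate columns).
#' @export
make_msa <- function(n_seqs = 50, n_conserved = 20, n_variable = 20,
                     n_intermediate = 50, gap_fraction = 0, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(n_seqs >= 2)
  n_col <- n_conserved + n_variable + n_intermediate
  pool <- c("A", "R", "N", "D", "E", "G", "I", "L", "S", "V")
  gap_fraction <- rep_len(gap_fraction, n_col)
  with_seed(seed, {
    labels <- sample(c(rep("conserved", n_conserved),
                       rep("variable", n_variable),
                       rep("intermediate", n_intermediate)))
    m <- matrix("-", nrow = n_seqs, ncol = n_col)
    dominant <- rep(NA_character_, n_col)
    for (j in seq_len(n_col)) {
      col <- switch(labels[j],
        conserved = {
          dominant[j] <- sample(AMINO_ACIDS, 1)
          rep(dominant[j], n_seqs)
        },
        # balanced multisets (rather than i.i.d. draws) pin each column's
        # composition to its planted level, so the score ladder
        # variable < intermediate < conserved holds at any sample size
        variable = sample(rep_len(pool, n_seqs)),
        intermediate = {
          dominant[j] <- sample(AMINO_ACIDS, 1)
          f <- stats::runif(1, 0.6, 0.8)
          k <- round(f * n_seqs)
          sample(c(rep(dominant[j], k), rep_len(pool, n_seqs - k)))
        })
      if (gap_fraction[j] > 0) {
        n_gap <- round(gap_fraction[j] * n_seqs)
        col[sample.int(n_seqs, n_gap)] <- "-"
      }
      m[, j] <- col
    }
    ids <- sprintf("seq%03d", seq_len(n_seqs))
    rownames(m) <- ids
    list(msa = structure(list(ids = ids, seqs = m), class = "kinase_msa"),
         labels = labels, dominant = dominant)
  })
}

# NeRF internal-coordinate placement: position d so that |c-d| = bond,
# angle(b,c,d) = angle_deg and torsion(a,b,c,d) = torsion_deg.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  d_local <- c(-bond * cos(th), bond * cos(ph) * sin(th),
               bond * sin(ph) * sin(th))
  bc <- (c - b) / sqrt(sum((c - b)^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  as.numeric(c + cbind(bc, m, n) %*% d_local)
}

IDEAL_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
                   ang_n_ca_c = 111.0, ang_ca_c_n = 117.0,
                   ang_c_n_ca = 121.0, omega = 180)

# Build an N/CA/C backbone with the requested Phi/Psi torsions, ideal bond
# lengths and angles; returns a data.frame of atoms.
build_backbone <- function(n_res, phi, psi, resno, chain = "A",
                           resid = rep("ALA", n_res)) {
  g <- IDEAL_GEOM
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  atoms <- vector("list", n_res)
  n <- c(0, 0, 0)
  ca <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  cc <- ca + c(-cos(th), sin(th), 0) * g$ca_c
  atoms[[1]] <- rbind(n, ca, cc)
  if (n_res >= 2) for (i in 2:n_res) {
    prev <- atoms[[i - 1]]
    n_i <- place_atom(prev[1, ], prev[2, ], prev[3, ], g$c_n, g$ang_ca_c_n,
                      psi[i - 1])
    ca_i <- place_atom(prev[2, ], prev[3, ], n_i, g$n_ca, g$ang_c_n_ca,
                       g$omega)
    c_i <- place_atom(prev[3, ], n_i, ca_i, g$ca_c, g$ang_n_ca_c, phi[i])
    atoms[[i]] <- rbind(n_i, ca_i, c_i)
  }
  do.call(rbind, lapply(seq_len(n_res), function(i) {
    xyz <- atoms[[i]]
    data.frame(chain = chain, resno = resno[i], resid = resid[i],
               elety = c("N", "CA", "C"), element = c("N", "C", "C"),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }))
}

# CB off the backbone frame of one residue (rows: N, CA, C xyz)
place_cb <- function(n, ca, cc) place_atom(cc, n, ca, 1.53, 110.5, 122.5)

#' Synthetic structure with planted geometry
#'
#' Builds a poly-alanine backbone by sequential internal-coordinate
#' placement (ideal bond lengths/angles, torsions set to the targets), so
#' measured Phi/Psi equal the planted values to numerical precision.
#' Optionally plants a cysteine disulfide at an exact SG-SG distance and an
#' anchor set realizing stated D1/D2/Lys-Glu distances. The anchor residues
#' are placed as free-standing residue islands positioned purely to satisfy
#' the distance constraints; the result is a measurement fixture, not a
#' physically realistic fold.
#'
#' @param n_res Number of backbone residues.
#' @param phi,psi Target torsions in degrees, recycled along the chain
#'   (`phi[1]` and `psi[n_res]` are undefined at the termini and ignored).
#' @param resno_start First author residue number.
#' @param chain Chain id.
#' @param disulfide Optional `list(residues = c(i, j), distance = 2.05)`:
#'   the two residues (author numbers, within the chain) become CYS with SG
#'   atoms at exactly `distance` Angstrom.
#' @param anchor_distances Optional
#'   `list(d1 =, d2 =, lys_glu =, resno = c(lys =, glu =, d1_anchor =,
#'   phe =))` planting the three diagnostic distances; the `phe` residue
#'   must lie in the chain and receives a CZ atom. Infeasible distance
#'   combinations (violating the triangle inequality) are an error.
#' @param seed Integer seed (required; the builder itself is deterministic
#'   but the seed fixes any sampled orientations).
#' @return List with `model` (a `structure_model`) and `truth` (planted
#'   values).
#' @export
make_structure <- function(n_res = 7, phi = -60, psi = -45, resno_start = 1,
                           chain = "A", disulfide = NULL,
                           anchor_distances = NULL, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  if (any(phi <= -180 | phi > 180) || any(psi <= -180 | psi > 180)) {
    stop("target dihedrals must lie in (-180, 180]")
  }
  resno <- resno_start + seq_len(n_res) - 1
  resid <- rep("ALA", n_res)
  truth <- list(phi = phi, psi = psi, resno = resno)
  with_seed(seed, {
    if (!is.null(disulfide)) {
      resid[match(disulfide$residues, resno)] <- "CYS"
    }
    if (!is.null(anchor_distances) &&
        anchor_distances$resno[["phe"]] %in% resno) {
      resid[match(anchor_distances$resno[["phe"]], resno)] <- "PHE"
    }
    atoms <- build_backbone(n_res, phi, psi, resno, chain, resid)

    add_atom <- function(atoms, resno_i, resid_i, elety, element, xyz) {
      rbind(atoms, data.frame(chain = chain, resno = resno_i,
                              resid = resid_i, elety = elety,
                              element = element, x = xyz[1], y = xyz[2],
                              z = xyz[3], stringsAsFactors = FALSE))
    }
    res_xyz <- function(atoms, r, ety) {
      i <- which(atoms$resno == r & atoms$elety == ety)
      as.numeric(atoms[i[1], c("x", "y", "z")])
    }

    if (!is.null(disulfide)) {
      rs <- disulfide$residues
      dd <- if (is.null(disulfide$distance)) 2.05 else disulfide$distance
      if (!all(rs %in% resno)) stop("disulfide residues outside the chain")
      cbs <- sgs <- list()
      for (k in 1:2) {
        r <- rs[k]
        nb <- res_xyz(atoms, r, "N"); cab <- res_xyz(atoms, r, "CA")
        ccb <- res_xyz(atoms, r, "C")
        cb <- place_cb(nb, cab, ccb)
        atoms <- add_atom(atoms, r, "CYS", "CB", "C", cb)
        cbs[[k]] <- cb
        sgs[[k]] <- place_atom(nb, cab, cb, 1.81, 114, 180)
      }
      # keep SG1 as built; put SG2 exactly dd away, toward CB2 so the
      # sulfur stays on the second residue's side
      u <- cbs[[2]] - sgs[[1]]
      un <- sqrt(sum(u^2))
      u <- if (un < 1e-9) c(0, 0, 1) else u / un
      sg2 <- sgs[[1]] + dd * u
      atoms <- add_atom(atoms, rs[1], "CYS", "SG", "S", sgs[[1]])
      atoms <- add_atom(atoms, rs[2], "CYS", "SG", "S", sg2)
      truth$sg_distance <- dd
      truth$disulfide <- rs
    }

    if (!is.null(anchor_distances)) {
      ad <- anchor_distances
      d1 <- ad$d1; d2 <- ad$d2; dk <- ad$lys_glu
      if (!all(is.finite(c(d1, d2, dk))) || any(c(d1, d2, dk) <= 0)) {
        stop("infeasible anchor distance constraints: ",
             "distances must be positive and finite")
      }
      an <- ad$resno
      if (!an[["phe"]] %in% resno) stop("anchor 'phe' must lie in the chain")
      # free-standing islands, offset well away from the chain
      base <- c(60, 0, 0)
      island <- function(r, name3, at) {
        bb <- build_backbone(1, -60, -45, r, chain, name3)
        bb$x <- bb$x + at[1]; bb$y <- bb$y + at[2]; bb$z <- bb$z + at[3]
        bb
      }
      d_ca <- max(d1, d2)  # guarantees the two spheres intersect
      if (abs(d1 - d2) > d_ca || d_ca > d1 + d2 ||
          d2^2 < ((d_ca^2 + d2^2 - d1^2) / (2 * d_ca))^2) {
        stop("infeasible anchor distance constraints")
      }
      lys <- island(an[["lys"]], "LYS", base)
      ca_lys <- as.numeric(lys[lys$elety == "CA", c("x", "y", "z")])
      anchor68 <- island(an[["d1_anchor"]], "LEU", base + c(d_ca, 0, 0))
      ca_68 <- as.numeric(anchor68[anchor68$elety == "CA",
                                   c("x", "y", "z")])
      glu <- island(an[["glu"]], "GLU", base + c(0, -8, 0))
      atoms <- rbind(atoms, lys, anchor68, glu)
      # CBs for the Lys-Glu salt-bridge distance
      cb_lys <- place_cb(res_xyz(atoms, an[["lys"]], "N"), ca_lys,
                         res_xyz(atoms, an[["lys"]], "C"))
      atoms <- add_atom(atoms, an[["lys"]], "LYS", "CB", "C", cb_lys)
      u <- c(0, 0, 1)
      cb_glu <- cb_lys + dk * u
      atoms <- add_atom(atoms, an[["glu"]], "GLU", "CB", "C", cb_glu)
      # CZ solving |CZ-ca_68| = d1 and |CZ-ca_lys| = d2
      xloc <- (d_ca^2 + d2^2 - d1^2) / (2 * d_ca)
      yloc <- sqrt(max(d2^2 - xloc^2, 0))
      ex <- (ca_68 - ca_lys) / d_ca
      ey <- c(-ex[2], ex[1], 0)
      if (sqrt(sum(ey^2)) < 1e-9) ey <- c(0, 1, 0)
      ey <- ey / sqrt(sum(ey^2))
      cz <- ca_lys + xloc * ex + yloc * ey
      atoms <- add_atom(atoms, an[["phe"]], "PHE", "CZ", "C", cz)
      truth$d1 <- d1; truth$d2 <- d2; truth$lys_glu <- dk
      truth$anchor_resno <- an
    }
    list(model = structure_model(atoms, "synthetic"), truth = truth)
  })
}

#' Synthetic binding or dose-response curve
#'
#' Concentrations come from [dilution_series()]; responses from the chosen
#' model plus seeded Gaussian noise, with `n_replicates` independent
#' measurements per concentration.
#'
#' @param model `"total-binding"` or `"dose-response"`.
#' @param params Named list of generating parameters (`bmax`, `kd`, `ns`,
#'   `background`, or `top`, `bottom`, `ic50`, `hill`).
#' @param top,factor,n_points Dilution-series design (defaults 250, 2, 16).
#' @param sigma Gaussian noise standard deviation in response units
#'   (default 0).
#' @param n_replicates Technical replicates per concentration (default 2).
#' @param seed Integer seed (required).
#' @return List with `curve` (a [binding_curve()]) and `params`.
#' @export
make_curve <- function(model = c("total-binding", "dose-response"),
                       params, top = 250, factor = 2, n_points = 16,
                       sigma = 0, n_replicates = 2, seed) {
  if (missing(seed)) stop("an explicit integer seed is required")
  model <- match.arg(model)
  stopifnot(sigma >= 0)
  x1 <- dilution_series(top, factor, n_points)
  x <- rep(x1, each = n_replicates)
  mu <- if (model == "total-binding") {
    total_binding_predict(x, params$bmax, params$kd, params$ns,
                          params$background)
  } else {
    dose_response_predict(x, params$top, params$bottom, params$ic50,
                          params$hill)
  }
  with_seed(seed, {
    y <- mu + stats::rnorm(length(mu), 0, sigma)
    list(curve = binding_curve(x, y,
                               replicate = rep(seq_len(n_replicates),
                                               times = n_points)),
         params = params)
  })
}
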