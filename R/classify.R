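#' Kinase anchor residues
#'
#' Maps the structural roles used by the conformational measurements to
#' author residue numbers. Defaults are the AMPKalpha2 kinase domain: beta3
#' Lys45, alphaC Glu64, D1 anchor Leu68 (the alphaC-Glu+4 position), DFG
#' triad Asp157-Phe158-Gly159, x-DFG-x window Ala156-Leu160, gatekeeper
#' Met93, HRD His137, lower regulatory-spine residues (DFG Phe158, HRD
#' His137, alphaF Asp196), and the Cys106/Cys174 disulfide candidates.
#' Author (PDB) numbering is used throughout; no renumbering.
#'
#' @param beta3_lysine,alphaC_glutamate,d1_anchor,gatekeeper,hrd_histidine
#'   Single residue numbers.
#' @param dfg Length-3 vector: Asp, Phe, Gly residue numbers.
#' @param xdfgx_span Length-5 vector of the x-DFG-x residues.
#' @param spine_residues Ordered residue numbers of the regulatory spine.
#' @param disulfide_candidates List of length-2 residue-number vectors.
#' @param chain_id Chain to measure on (default `"A"`).
#' @return An object of class `kinase_anchors`.
#' @export
kinase_anchors <- function(beta3_lysine = 45, alphaC_glutamate = 64,
                           d1_anchor = 68, dfg = c(157, 158, 159),
                           xdfgx_span = 156:160, gatekeeper = 93,
                           hrd_histidine = 137,
                           spine_residues = c(158, 137, 196),
                           disulfide_candidates = list(c(106, 174)),
                           chain_id = "A") {
  stopifnot(length(dfg) == 3, length(xdfgx_span) == 5)
  structure(list(beta3_lysine = beta3_lysine,
                 alphaC_glutamate = alphaC_glutamate,
                 d1_anchor = d1_anchor,
                 dfg_asp = dfg[1], dfg_phe = dfg[2], dfg_gly = dfg[3],
                 xdfgx_span = xdfgx_span, gatekeeper = gatekeeper,
                 hrd_histidine = hrd_histidine,
                 spine_residues = spine_residues,
                 disulfide_candidates = disulfide_candidates,
                 chain_id = chain_id),
            class = "kinase_anchors")
}

#' Geometric conformation report for one structure
#'
#' Computes the quantities that define a kinase's conformational state:
#' D1 (D1-anchor CA to DFG-Phe CZ), D2 (beta3-Lys CA to DFG-Phe CZ), the
#' Lys-Glu salt-bridge CB-CB distance, Phi/Psi over the x-DFG-x window,
#' disulfide bridges, and regulatory-spine contact status.
#'
#' @param model A `structure_model`.
#' @param anchors A [kinase_anchors()] object resolvable in `model`.
#' @param max_sg_distance Disulfide SG-SG cutoff (default 2.3 Angstrom).
#' @param contact_cutoff Spine contact cutoff (default 4.5 Angstrom).
#' @return List of class `geometry_report` with elements `structure_id`,
#'   `d1`, `d2`, `lys_glu_distance` (Angstrom, full precision),
#'   `xdfgx_dihedrals`, `disulfides`, `spine`, and the `anchors` used.
#' @export
geometry_report <- function(model, anchors = kinase_anchors(),
                            max_sg_distance = 2.3, contact_cutoff = 4.5) {
  ch <- anchors$chain_id
  rep_ <- list(
    structure_id = attr(model, "structure_id"),
    d1 = atom_distance(model,
                       list(chain = ch, resno = anchors$d1_anchor,
                            elety = "CA"),
                       list(chain = ch, resno = anchors$dfg_phe,
                            elety = "CZ")),
    d2 = atom_distance(model,
                       list(chain = ch, resno = anchors$beta3_lysine,
                            elety = "CA"),
                       list(chain = ch, resno = anchors$dfg_phe,
                            elety = "CZ")),
    lys_glu_distance = atom_distance(model,
                       list(chain = ch, resno = anchors$beta3_lysine,
                            elety = "CB"),
                       list(chain = ch, resno = anchors$alphaC_glutamate,
                            elety = "CB")),
    xdfgx_dihedrals = backbone_dihedrals(model, ch, anchors$xdfgx_span),
    disulfides = detect_disulfides(model, max_sg_distance),
    spine = spine_contacts(model, anchors$spine_residues, ch,
                           contact_cutoff),
    anchors = anchors)
  class(rep_) <- "geometry_report"
  rep_
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("Geometry report for %s\n", x$structure_id))
  cat(sprintf("  D1 %.1f A  D2 %.1f A  Lys-Glu %.1f A  spine %s  %d disulfide(s)\n",
              x$d1, x$d2, x$lys_glu_distance, x$spine$status,
              nrow(x$disulfides)))
  invisible(x)
}

#' Default conformational decision thresholds
#'
#' Decision constants for the spatial DFG label and the alphaC label. The
#' D1/D2 boundaries are stand-ins chosen so the canonical DFG-in range (D1
#' around 11-13, D2 around 16-19 Angstrom) labels DFG-in; they are data, are
#' echoed in every call, and should be adjusted if a published boundary set
#' is preferred.
#'
#' @return Named list: `d2_out_max` (DFG-out when D2 at or below this),
#'   `d2_in_min`, `d2_d1_margin` (DFG-in needs `d2 >= d2_in_min` and
#'   `d2 - d1 >= d2_d1_margin`), `alphaC_cutoff` (out when Lys-Glu distance
#'   strictly exceeds this), `assignment_cutoff` (mean circular distance in
#'   degrees above which a dihedral set is unassigned).
#' @export
default_thresholds <- function() {
  list(d2_out_max = 11, d2_in_min = 11, d2_d1_margin = 2,
       alphaC_cutoff = 10, assignment_cutoff = 45)
}

#' Spatial DFG label from the D1/D2 distances
#'
#' Default rule: DFG-out when `d2 <= d2_out_max`; DFG-in when
#' `d2 >= d2_in_min` and `d2 - d1 >= d2_d1_margin`; otherwise DFG-inter.
#' A pure function of its inputs: the thresholds used are echoed so the call
#' is reproducible.
#'
#' @param d1,d2 Distances in Angstrom (positive).
#' @param thresholds See [default_thresholds()].
#' @return List with `label` (one of `"DFG-in"`, `"DFG-out"`, `"DFG-inter"`)
#'   and `thresholds_used`.
#' @export
spatial_label <- function(d1, d2, thresholds = default_thresholds()) {
  stopifnot(d1 > 0, d2 > 0)
  label <- if (d2 <= thresholds$d2_out_max) "DFG-out"
           else if (d2 >= thresholds$d2_in_min &&
                    (d2 - d1) >= thresholds$d2_d1_margin) "DFG-in"
           else "DFG-inter"
  list(label = label, thresholds_used = thresholds)
}

#' alphaC helix in/out label from the Lys-Glu distance
#'
#' The alphaC helix is called *out* when the beta3-Lys / alphaC-Glu CB-CB
#' distance strictly exceeds the cutoff (default 10 Angstrom); the boundary
#' itself is *in*.
#'
#' @param lys_glu_distance Distance in Angstrom (positive).
#' @param cutoff Cutoff in Angstrom (default 10).
#' @return `"in"` or `"out"`.
#' @export
alphaC_label <- function(lys_glu_distance, cutoff = 10) {
  stopifnot(lys_glu_distance > 0)
  if (lys_glu_distance > cutoff) "out" else "in"
}

#' Illustrative x-DFG-x dihedral cluster library
#'
#' A small editable library of named dihedral-cluster centroids (Phi/Psi for
#' the five x-DFG-x residues). These centroids are illustrative defaults
#' curated to represent textbook DFG-in active, DFG-in inactive and DFG-out
#' states; replace them with a published centroid table for production
#' assignments. The library is data, not code.
#'
#' @param assignment_cutoff Mean per-angle circular distance (degrees) above
#'   which a structure is left `"unassigned"` (default 45).
#' @return Object of class `dihedral_cluster_library`: list with `clusters`
#'   (named list of 5 x 2 matrices, columns phi/psi) and
#'   `assignment_cutoff`.
#' @export
default_cluster_library <- function(assignment_cutoff = 45) {
  mk <- function(phi, psi) cbind(phi = phi, psi = psi)
  lib <- list(
    "DFG-in-active"  = mk(c(-120, -65, -60, 85, -110),
                          c(150, 140, -25, 5, 10)),
    "DFG-in-BLB"     = mk(c(-125, -60, -75, 130, -100),
                          c(160, 135, 170, 5, 20)),
    "DFG-out-classic" = mk(c(-85, 60, -90, -80, -130),
                           c(135, 80, 0, -35, 160))
  )
  structure(list(clusters = lib, assignment_cutoff = assignment_cutoff),
            class = "dihedral_cluster_library")
}

circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Assign an x-DFG-x dihedral set to a cluster
#'
#' Computes the mean circular distance (respecting wraparound at +/-180
#' degrees) between the observed Phi/Psi angles and each cluster centroid,
#' over the angles that are defined; missing angles (chain termini) are
#' dropped with weight renormalization. The nearest centroid wins unless its
#' mean distance exceeds the library's `assignment_cutoff`, in which case the
#' structure is `"unassigned"`.
#'
#' @param xdfgx `data.frame` from [backbone_dihedrals()] with five rows
#'   (`phi`, `psi` columns).
#' @param library A [default_cluster_library()]-style library.
#' @return List with `cluster` (name or `"unassigned"`), `distance` (mean
#'   circular distance to the best centroid), `second_best` and
#'   `second_distance`.
#' @export
dihedral_cluster <- function(xdfgx, library = default_cluster_library()) {
  if (length(library$clusters) == 0) stop("empty dihedral cluster library")
  obs <- c(xdfgx$phi, xdfgx$psi)
  dists <- vapply(library$clusters, function(cen) {
    cenv <- c(cen[, "phi"], cen[, "psi"])
    ok <- !is.na(obs)
    if (!any(ok)) return(NA_real_)
    mean(circular_distance(obs[ok], cenv[ok]))
  }, numeric(1))
  cluster_names <- names(dists)
  dists <- unname(dists)
  ord <- order(dists)
  best <- ord[1]
  list(cluster = if (is.na(dists[best]) ||
                     dists[best] > library$assignment_cutoff) "unassigned"
                 else cluster_names[best],
       distance = dists[best],
       second_best = if (length(dists) > 1) cluster_names[ord[2]]
                     else NA_character_,
       second_distance = if (length(dists) > 1) dists[ord[2]] else NA_real_)
}

#' Full conformational call for a structure
#'
#' Composes the geometry report with the three classification rules: spatial
#' DFG label from (D1, D2), alphaC in/out from the Lys-Glu distance, and
#' dihedral-cluster assignment of the x-DFG-x window. Deterministic: the
#' full geometry report and all thresholds used are embedded in the output.
#'
#' @param model A `structure_model`.
#' @param anchors A [kinase_anchors()] object.
#' @param library Dihedral cluster library.
#' @param thresholds Decision constants, see [default_thresholds()].
#' @return List of class `conformation_call` with `spatial_label`,
#'   `alphaC_label`, `dihedral_cluster`, the measured `d1`, `d2`,
#'   `lys_glu_distance`, `thresholds_used`, and the embedded `geometry`.
#' @export
classify_conformation <- function(model, anchors = kinase_anchors(),
                                  library = default_cluster_library(),
                                  thresholds = default_thresholds()) {
  geo <- geometry_report(model, anchors)
  sp <- spatial_label(geo$d1, geo$d2, thresholds)
  cl <- dihedral_cluster(geo$xdfgx_dihedrals, library)
  out <- list(spatial_label = sp$label,
              alphaC_label = alphaC_label(geo$lys_glu_distance,
                                          thresholds$alphaC_cutoff),
              dihedral_cluster = cl$cluster,
              cluster_distance = cl$distance,
              d1 = geo$d1, d2 = geo$d2,
              lys_glu_distance = geo$lys_glu_distance,
              thresholds_used = thresholds,
              geometry = geo)
  class(out) <- "conformation_call"
  out
}

#' @export
print.conformation_call <- function(x, ...) {
  cat(sprintf("%s: %s, alphaC-%s, dihedral cluster: %s\n",
              x$geometry$structure_id, x$spatial_label, x$alphaC_label,
              x$dihedral_cluster))
  cat(sprintf("  D1 %.1f A, D2 %.1f A, Lys-Glu %.1f A\n",
              x$d1, x$d2, x$lys_glu_distance))
  invisible(x)
}
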