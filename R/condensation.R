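# Chromosome-condensation scoring against a fixed circular ROI mask.
#
# The assay: segment DAPI-stained DNA masses, drop masses whose boundaries
# are obscured by a neighbour (omitted from quantification), strip thin
# rDNA-loop protrusions, then superimpose a fixed-size circular mask on
# each remaining mass and call it "matched" when it either covers most of
# the mask area or contacts the majority of the mask's edge. The per-field
# readout is the percentage of scorable masses that matched the template;
# hypercondensed masses occupy a smaller area and fail.

#' Specify the circular ROI mask and match criteria
#'
#' @param diameter_px Mask circle diameter (default 62 px, matched to a
#'   wildtype preanaphase DNA mass).
#' @param edge_fraction Minimum fraction of mask-boundary pixels that must
#'   lie within `edge_tolerance_px` of the mass (default 0.75, the
#'   "majority of the edges" criterion).
#' @param fill_fraction Minimum covered fraction of the mask area for the
#'   fill criterion (default 0.90; exact 1.0 would fail on antialiased
#'   edges).
#' @param edge_tolerance_px Tolerance band for edge coincidence.
#' @return A list of class `mask_spec`.
#' @export
mask_spec <- function(diameter_px = 62, edge_fraction = 0.75,
                      fill_fraction = 0.90, edge_tolerance_px = 2) {
  if (diameter_px < 3) stop_usage("diameter_px must be >= 3")
  if (edge_fraction <= 0 || edge_fraction > 1 ||
      fill_fraction <= 0 || fill_fraction > 1) {
    stop_usage("edge_fraction and fill_fraction must lie in (0, 1]")
  }
  spec <- list(diameter_px = diameter_px, edge_fraction = edge_fraction,
               fill_fraction = fill_fraction,
               edge_tolerance_px = edge_tolerance_px)
  class(spec) <- "mask_spec"
  spec
}

# 8-connected labeling of a binary matrix (EBImage::bwlabel is
# 4-connected). Components are found on the 8-neighbour pixel graph.
label_components8 <- function(binary) {
  idx <- which(binary > 0)
  lab <- matrix(0L, nrow(binary), ncol(binary))
  if (length(idx) == 0) return(lab)
  nr <- nrow(binary)
  nc <- ncol(binary)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  id_of <- integer(nr * nc)
  id_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- id_of[nb] > 0
    edges <- c(edges, rbind(which(ok)[hit], id_of[nb][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Segment DNA masses in a grayscale field
#'
#' Thresholds the image (Otsu or fixed), labels 8-connected components of
#' at least `min_area_px` pixels, and flags masses whose dilated
#' footprints touch another mass as `omitted_overlap` (obscured genomic
#' boundaries are excluded from quantification). A blank image yields an
#' empty result, not an error.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Threshold value for `"fixed"` (default 0.4, half the
#'   rendering amplitude of [render_field()]).
#' @param min_area_px Minimum component area in pixels.
#' @param overlap_dilate_px Dilation radius used to detect near-touching
#'   masses.
#' @return A list of class `mass_segmentation`: `labels` (integer
#'   matrix), `masses` (tibble `mass_id`, `area_px`, `cx`, `cy`,
#'   `status`).
#' @export
segment_masses <- function(image, threshold_method = c("otsu", "fixed"),
                           threshold = 0.4, min_area_px = 50,
                           overlap_dilate_px = 5) {
  threshold_method <- match.arg(threshold_method)
  if (length(dim(image)) != 2) stop_usage("image must be a 2-D matrix")
  thr <- if (threshold_method == "otsu") {
    rng <- range(image)
    if (diff(rng) < .Machine$double.eps) Inf  # flat image: nothing above
    else EBImage::otsu(EBImage::Image(image), range = rng)
  } else {
    threshold
  }
  binary <- (image > thr) * 1L
  lab <- label_components8(binary)
  n <- max(lab)
  if (n == 0) {
    return(structure(list(labels = lab,
                          masses = tibble(mass_id = integer(0),
                                          area_px = integer(0),
                                          cx = numeric(0), cy = numeric(0),
                                          status = character(0))),
                     class = "mass_segmentation"))
  }
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= min_area_px)
  lab[!(lab %in% keep)] <- 0L
  # relabel 1..n_keep preserving order
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  n <- length(keep)
  if (n == 0) {
    return(structure(list(labels = lab,
                          masses = tibble(mass_id = integer(0),
                                          area_px = integer(0),
                                          cx = numeric(0), cy = numeric(0),
                                          status = character(0))),
                     class = "mass_segmentation"))
  }
  # overlap detection: masses merging under dilation share a component
  brush_size <- 2 * ceiling(overlap_dilate_px) + 1
  dil <- EBImage::dilate(EBImage::Image((lab > 0) * 1),
                         EBImage::makeBrush(brush_size, "disc"))
  dil_lab <- label_components8(EBImage::imageData(dil))
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  comp_of_mass <- vapply(seq_len(n), function(i) {
    dil_lab[idx[lab[idx] == i][1]]
  }, integer(1))
  shared <- comp_of_mass %in% comp_of_mass[duplicated(comp_of_mass)]
  masses <- tibble(
    mass_id = seq_len(n),
    area_px = vapply(seq_len(n), function(i) sum(lab == i), integer(1)),
    cx = vapply(seq_len(n), function(i) mean(cols[lab[idx] == i]), numeric(1)),
    cy = vapply(seq_len(n), function(i) mean(rows[lab[idx] == i]), numeric(1)),
    status = ifelse(shared, "omitted_overlap", "pending")
  )
  structure(list(labels = lab, masses = masses), class = "mass_segmentation")
}

#' Strip thin protrusions from a mass
#'
#' Morphological opening with a disc of diameter `max_width_px` removes
#' attached structures thinner than `max_width_px` (the rDNA-loop
#' extensions excluded from area scoring); the largest remaining
#' 8-connected component is returned as the mass core. A mass entirely
#' thinner than the disc opens to nothing and is unscorable (`NULL`).
#'
#' @param mass Binary matrix (one mass).
#' @param max_width_px Width cutoff in pixels (default 7).
#' @return Binary matrix of the core, with attribute `pruned` (TRUE when
#'   more than 1 percent of the mass area was removed; opening also shaves
#'   a sub-percent rim off any rasterized shape, which does not count), or
#'   `NULL` when nothing survives.
#' @export
prune_protrusions <- function(mass, max_width_px = 7) {
  if (sum(mass) == 0) stop_usage("mass is empty")
  size <- max(3L, 2L * floor(max_width_px / 2) + 1L)
  opened <- EBImage::opening(EBImage::Image(mass * 1),
                             EBImage::makeBrush(size, "disc"))
  opened <- EBImage::imageData(opened)
  if (sum(opened) == 0) return(NULL)
  lab <- label_components8(opened)
  areas <- tabulate(lab[lab > 0])
  core <- (lab == which.max(areas)) * 1L
  attr(core, "pruned") <- (sum(mass) - sum(core)) > 0.01 * sum(mass)
  core
}

#' Classify one mass core against the circular ROI mask
#'
#' Centres the mask circle on the core centroid and calls the mass
#' `matched` when the core covers at least `fill_fraction` of the mask
#' area, or when at least `edge_fraction` of the mask-boundary pixels lie
#' within `edge_tolerance_px` of a core pixel; otherwise `failed`.
#'
#' @param core Binary matrix from [prune_protrusions()] (or any nonempty
#'   binary mass).
#' @param mask A [mask_spec()].
#' @return `"matched"` or `"failed"`, with attributes `fill` and
#'   `edge_coincidence` carrying the two measured fractions.
#' @export
classify_mass <- function(core, mask = mask_spec()) {
  if (sum(core) == 0) stop_usage("core is empty")
  idx <- which(core > 0)
  nr <- nrow(core)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  cy <- mean(rows); cx <- mean(cols)
  R <- mask$diameter_px / 2
  # mask disc and 1-px boundary ring on the pixel grid
  rr <- seq(floor(cy - R - 1), ceiling(cy + R + 1))
  cc <- seq(floor(cx - R - 1), ceiling(cx + R + 1))
  grid_r <- rep(rr, times = length(cc))
  grid_c <- rep(cc, each = length(rr))
  dist <- sqrt((grid_r - cy)^2 + (grid_c - cx)^2)
  in_disc <- dist <= R
  on_ring <- dist > R - 1 & dist <= R
  inside_img <- grid_r >= 1 & grid_r <= nr & grid_c >= 1 & grid_c <= ncol(core)
  covered <- logical(length(grid_r))
  ok <- inside_img
  covered[ok] <- core[cbind(grid_r[ok], grid_c[ok])] > 0
  fill <- sum(covered & in_disc) / sum(in_disc)
  # distance from each ring pixel to the nearest core pixel
  ring_r <- grid_r[on_ring]; ring_c <- grid_c[on_ring]
  tol <- mask$edge_tolerance_px
  near <- vapply(seq_along(ring_r), function(i) {
    min((rows - ring_r[i])^2 + (cols - ring_c[i])^2) <= tol^2
  }, logical(1))
  edge_frac <- mean(near)
  status <- if (fill >= mask$fill_fraction || edge_frac >= mask$edge_fraction) {
    "matched"
  } else {
    "failed"
  }
  structure(status, fill = fill, edge_coincidence = edge_frac)
}

#' Score fields against the ROI mask
#'
#' Runs the full assay on each field: segmentation, overlap omission,
#' protrusion pruning and mask classification, then summarises per field
#' and pools matched/scored counts across fields (replicate counts are
#' pooled the way replicate experiments report a combined n).
#'
#' @param fields A list of `nucleus_field` objects, numeric matrices, or
#'   image file paths (mixing is allowed).
#' @param mask A [mask_spec()].
#' @param threshold_method,threshold,min_area_px Passed to
#'   [segment_masses()].
#' @param prune_width_px Protrusion width cutoff for
#'   [prune_protrusions()].
#' @return A list of class `condensation_result`: `per_field` (tibble
#'   `field_id`, `n_scored`, `n_matched`, `percent_matched`), `per_mass`
#'   (tibble with each mass's `area_px`, `status`, `loop_pruned`), and
#'   `pooled` (list `n_scored`, `n_matched`, `percent_matched`). Fields
#'   with zero scorable masses are excluded with a warning.
#' @export
score_fields <- function(fields, mask = mask_spec(),
                         threshold_method = "fixed", threshold = 0.4,
                         min_area_px = 50, prune_width_px = 7) {
  if (length(fields) == 0) stop_usage("need at least one field")
  if (!is.list(fields) || inherits(fields, "nucleus_field")) {
    fields <- list(fields)
  }
  per_field <- list()
  per_mass <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (inherits(f, "nucleus_field")) {
      img <- f$image; fid <- f$field_id
    } else if (is.character(f)) {
      img <- read_field_image(f); fid <- basename(f)
    } else {
      img <- f; fid <- names(fields)[i] %||% paste0("field", i)
      if (is.null(names(fields)) || fid == "") fid <- paste0("field", i)
    }
    seg <- segment_masses(img, threshold_method = threshold_method,
                          threshold = threshold, min_area_px = min_area_px)
    calls <- seg$masses
    calls$loop_pruned <- FALSE
    for (j in seq_len(nrow(calls))) {
      if (calls$status[j] == "omitted_overlap") next
      mass_bin <- (seg$labels == calls$mass_id[j]) * 1L
      core <- prune_protrusions(mass_bin, max_width_px = prune_width_px)
      if (is.null(core)) {
        calls$status[j] <- "unscorable"
        next
      }
      calls$loop_pruned[j] <- isTRUE(attr(core, "pruned"))
      calls$status[j] <- as.character(classify_mass(core, mask))
    }
    calls$field_id <- fid
    per_mass[[i]] <- calls
    n_scored <- sum(calls$status %in% c("matched", "failed"))
    if (n_scored == 0) {
      warning(sprintf("field %s has no scorable masses; excluded", fid))
      next
    }
    n_matched <- sum(calls$status == "matched")
    per_field[[length(per_field) + 1]] <- tibble(
      field_id = fid, n_scored = n_scored, n_matched = n_matched,
      percent_matched = 100 * n_matched / n_scored
    )
  }
  per_field <- bind_rows(per_field)
  per_mass <- bind_rows(per_mass)
  pooled <- list(
    n_scored = sum(per_field$n_scored),
    n_matched = sum(per_field$n_matched),
    percent_matched = if (nrow(per_field) > 0) {
      100 * sum(per_field$n_matched) / sum(per_field$n_scored)
    } else {
      NA_real_
    }
  )
  structure(list(per_field = per_field, per_mass = per_mass, pooled = pooled),
            class = "condensation_result")
}

#' @export
print.condensation_result <- function(x, ...) {
  cat(sprintf("<condensation_result> %d field(s), pooled %d/%d matched (%.1f%%)\n",
              nrow(x$per_field), x$pooled$n_matched, x$pooled$n_scored,
              x$pooled$percent_matched))
  print(x$per_field)
  invisible(x)
}

#' Write condensation results as CSV/JSON
#'
#' @param result A `condensation_result`.
#' @param mass_csv,field_csv,json_path Output paths (any may be `NULL`).
#' @return Invisibly, the result.
#' @export
write_condensation_result <- function(result, mass_csv = NULL,
                                      field_csv = NULL, json_path = NULL) {
  if (!is.null(mass_csv)) {
    utils::write.csv(result$per_mass[c("field_id", "mass_id", "area_px",
                                       "status", "loop_pruned")],
                     mass_csv, row.names = FALSE)
  }
  if (!is.null(field_csv)) {
    utils::write.csv(result$per_field, field_csv, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_field = result$per_field,
                              pooled = result$pooled),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
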