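# Hotspot-derived fire perimeters: two-step buffering of thermal-anomaly
# points into dissolved/contracted polygons, radius optimization against
# reference perimeters, ecozone calibration factors, polygon cleaning
# (water removal, minimum size), hybrid reference+buffered composites, and
# land-cover intersection.

#' Buffering parameters for hotspot-to-perimeter conversion
#'
#' @param r_out outward buffer radius (m)
#' @param r_in inward contraction radius (m); must satisfy
#'   \code{r_out > r_in >= 0}
#' @param ecozone optional ecozone id the parameters apply to
#' @export
buffer_params <- function(r_out, r_in, ecozone = NA) {
  if (!(r_out > r_in) || r_in < 0) stop("need r_out > r_in >= 0")
  structure(list(r_out = r_out, r_in = r_in, ecozone = ecozone),
            class = "buffer_params")
}

.fire_area_ha <- function(fire) length(fire$ids) * fire$frame$res^2 / 1e4

.perimeter_set <- function(fires) {
  structure(list(fires = fires), class = "perimeter_set")
}

#' Summary table of a perimeter set
#' @param x a \code{perimeter_set}
#' @param ... unused
#' @return data.frame with fire_id, source, ecozone, area_ha
#' @export
as.data.frame.perimeter_set <- function(x, ...) {
  data.frame(
    fire_id = vapply(x$fires, function(f) as.character(f$fire_id), ""),
    source = vapply(x$fires, function(f) f$source, ""),
    ecozone = vapply(x$fires, function(f) as.character(f$ecozone), ""),
    area_ha = vapply(x$fires, .fire_area_ha, 0)
  )
}

#' @export
print.perimeter_set <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<perimeter_set> %d fires, %.1f ha total\n",
              nrow(df), sum(df$area_ha)))
  invisible(x)
}

#' Two-step buffering of hotspots into perimeter polygons
#'
#' Buffers each hotspot outward by \code{r_out} metres, dissolves
#' intersecting discs, then contracts the dissolved polygons inward by
#' \code{r_in} metres (which may split or delete components). Hotspots are
#' grouped by \code{fire_id} when present; each group gets its own pixel
#' frame unless \code{frame} is supplied.
#'
#' @param hotspots data.frame with projected \code{x}, \code{y} (m) and
#'   optional \code{fire_id}, \code{ecozone}
#' @param params a \code{\link{buffer_params}}
#' @param res pixel size for the mask frames (m, default 30)
#' @param frame optional fixed \code{\link{pixel_frame}} (single group)
#' @return a \code{perimeter_set} with \code{source = "buffered"}
#' @export
buffer_hotspots <- function(hotspots, params, res = 30, frame = NULL) {
  stopifnot(inherits(params, "buffer_params"))
  if (nrow(hotspots) == 0) return(.perimeter_set(list()))
  if (is.null(hotspots$fire_id)) hotspots$fire_id <- "f1"
  fires <- list()
  for (fid in unique(hotspots$fire_id)) {
    h <- hotspots[hotspots$fire_id == fid, ]
    fr <- if (is.null(frame))
      frame_around(h$x, h$y, margin = params$r_out + 2 * res, res = res)
    else frame
    m <- .rasterize_discs(fr, h$x, h$y, params$r_out)
    m <- .erode_mask(fr, m, params$r_in)
    ids <- which(m)
    if (!length(ids)) next
    fires[[length(fires) + 1]] <- list(
      fire_id = fid, frame = fr, ids = ids, source = "buffered",
      ecozone = if (!is.null(h$ecozone)) h$ecozone[1] else NA)
  }
  .perimeter_set(fires)
}

.iou_for_candidate <- function(hots, refs, r_out, r_in, res) {
  inter <- 0; uni <- 0
  for (f in refs) {
    h <- hots[hots$fire_id == f$fire_id, ]
    if (!nrow(h)) next
    m <- .rasterize_discs(f$frame, h$x, h$y, r_out)
    m <- .erode_mask(f$frame, m, r_in)
    buf <- which(m)
    inter <- inter + length(intersect(buf, f$ids))
    uni <- uni + length(union(buf, f$ids))
  }
  if (uni == 0) 0 else inter / uni
}

#' Optimize buffer radii against reference perimeters, per ecozone
#'
#' Exhaustively evaluates every candidate \code{(r_out, r_in)} pair against
#' the reference perimeters of historical fires in each ecozone, scoring by
#' pooled intersection-over-union (maximizing intersecting area while
#' jointly minimizing commission and omission error). Ties break to the
#' smallest \code{r_out}, then the smallest \code{r_in}.
#'
#' @param hotspots data.frame with \code{x}, \code{y}, \code{fire_id}
#' @param reference \code{perimeter_set} of reference perimeters (fire_id and
#'   ecozone attributes set)
#' @param candidates data.frame of candidate \code{r_out}, \code{r_in} pairs
#' @return data.frame per ecozone: \code{ecozone}, \code{r_out}, \code{r_in},
#'   \code{iou}; ecozones without fires are omitted with a warning
#' @export
optimize_radii <- function(hotspots, reference, candidates) {
  stopifnot(nrow(candidates) >= 1, all(candidates$r_out > candidates$r_in))
  cand <- candidates[order(candidates$r_out, candidates$r_in), ]
  zones <- unique(vapply(reference$fires, function(f) as.character(f$ecozone), ""))
  out <- NULL
  for (z in zones) {
    refs <- Filter(function(f) identical(as.character(f$ecozone), z),
                   reference$fires)
    fids <- vapply(refs, function(f) as.character(f$fire_id), "")
    hz <- hotspots[hotspots$fire_id %in% fids, ]
    if (!nrow(hz)) { warning("ecozone ", z, ": no hotspots; skipped"); next }
    best <- NULL
    for (k in seq_len(nrow(cand))) {
      iou <- .iou_for_candidate(hz, refs, cand$r_out[k], cand$r_in[k],
                                refs[[1]]$frame$res)
      if (is.null(best) || iou > best$iou + 1e-12)
        best <- list(iou = iou, r_out = cand$r_out[k], r_in = cand$r_in[k])
    }
    out <- rbind(out, data.frame(ecozone = z, r_out = best$r_out,
                                 r_in = best$r_in, iou = best$iou))
  }
  out
}

#' Ecozone calibration factors from reference vs buffered areas
#'
#' Divides reference (mapped) burned area by buffered-hotspot burned area per
#' ecozone and year, then collapses years with an unweighted mean of the
#' yearly ratios (area-weighted pooling via \code{method = "pooled"}).
#'
#' @param areas data.frame with \code{ecozone}, \code{year},
#'   \code{ref_area_ha}, \code{buf_area_ha}
#' @param method \code{"mean_ratio"} (default) or \code{"pooled"}
#'   (sum of reference over sum of buffered)
#' @return data.frame per ecozone: \code{ecozone}, \code{factor},
#'   \code{n_years}
#' @export
calibration_factors <- function(areas, method = c("mean_ratio", "pooled")) {
  method <- match.arg(method)
  if (any(areas$buf_area_ha == 0)) {
    warning("strata with zero buffered area skipped")
    areas <- areas[areas$buf_area_ha > 0, ]
  }
  out <- NULL
  for (z in unique(areas$ecozone)) {
    a <- areas[areas$ecozone == z, ]
    f <- if (method == "mean_ratio") mean(a$ref_area_ha / a$buf_area_ha)
         else sum(a$ref_area_ha) / sum(a$buf_area_ha)
    out <- rbind(out, data.frame(ecozone = z, factor = f,
                                 n_years = nrow(a)))
  }
  out
}

#' Clean perimeter polygons: remove water and sub-threshold polygons
#'
#' Erases water bodies (given as circles in projected metres) from every
#' perimeter, then drops connected components smaller than
#' \code{min_area_ha}. Water removal precedes the size filter.
#'
#' @param perims a \code{perimeter_set}
#' @param water data.frame of water bodies: \code{cx}, \code{cy}, \code{r}
#'   (m); NULL for none
#' @param min_area_ha minimum polygon size retained (default 1 ha)
#' @return cleaned \code{perimeter_set}
#' @export
clean_polygons <- function(perims, water = NULL, min_area_ha = 1) {
  fires <- list()
  for (f in perims$fires) {
    m <- matrix(FALSE, f$frame$ny, f$frame$nx)
    m[f$ids] <- TRUE
    if (!is.null(water) && nrow(water)) {
      w <- .rasterize_discs(f$frame, water$cx, water$cy, water$r)
      m <- m & !w
    }
    if (any(m)) {
      lab <- .label_mask(m, 8)
      npix_min <- min_area_ha * 1e4 / f$frame$res^2
      keep <- which(tabulate(lab[lab > 0]) >= npix_min)
      m <- matrix(lab %in% keep, nrow(m), ncol(m))
    }
    if (!any(m)) next
    f$ids <- which(m)
    fires[[length(fires) + 1]] <- f
  }
  .perimeter_set(fires)
}

#' Merge reference and calibrated buffered perimeters into a hybrid composite
#'
#' Total burned area = sum of reference areas + sum of buffered areas
#' multiplied by their ecozone calibration factor. Every fire must appear in
#' exactly one source.
#'
#' @param reference \code{perimeter_set} of mapped (reference) perimeters
#' @param buffered \code{perimeter_set} of buffered perimeters
#' @param factors data.frame from \code{\link{calibration_factors}}
#' @return list: \code{table} (per-fire id, source, raw and calibrated area),
#'   \code{total_ha}
#' @export
merge_hybrid <- function(reference, buffered, factors) {
  rid <- vapply(reference$fires, function(f) as.character(f$fire_id), "")
  bid <- vapply(buffered$fires, function(f) as.character(f$fire_id), "")
  dup <- intersect(rid, bid)
  if (length(dup))
    stop("fire(s) present in both sources: ", paste(dup, collapse = ", "))
  rows <- list()
  for (f in reference$fires)
    rows[[length(rows) + 1]] <- data.frame(
      fire_id = as.character(f$fire_id), source = "reference",
      ecozone = as.character(f$ecozone),
      area_ha = .fire_area_ha(f), calibrated_ha = .fire_area_ha(f))
  for (f in buffered$fires) {
    fac <- factors$factor[match(as.character(f$ecozone), factors$ecozone)]
    if (is.na(fac)) stop("no calibration factor for ecozone ", f$ecozone)
    a <- .fire_area_ha(f)
    rows[[length(rows) + 1]] <- data.frame(
      fire_id = as.character(f$fire_id), source = "buffered",
      ecozone = as.character(f$ecozone),
      area_ha = a, calibrated_ha = a * fac)
  }
  tab <- do.call(rbind, rows)
  list(table = tab, total_ha = sum(tab$calibrated_ha))
}

#' Proportion of burned area by land-cover class and region
#'
#' Intersects perimeter pixels with a classified land-cover raster (nearest
#' cell lookup) and tallies burned area by class. Proportions are reported
#' over fuel classes; non-fuel classes are excluded from the denominator and
#' reported separately.
#'
#' @param perims a \code{perimeter_set}
#' @param landcover list with \code{frame} (a \code{\link{pixel_frame}}),
#'   \code{classes} (ny x nx integer matrix) and \code{class_names}
#' @param regions named vector mapping fire_id to region label (default: one
#'   region "all")
#' @param exclude class names treated as non-fuel (default Water, Rock)
#' @return list: \code{proportions} (region x class data.frame over fuel
#'   classes, rows sum to 1), \code{excluded} (region x class burned area of
#'   non-fuel classes, ha), \code{area_ha} (region x class, fuel classes)
#' @export
landcover_proportions <- function(perims, landcover, regions = NULL,
                                  exclude = c("Water", "Rock")) {
  cn <- landcover$class_names
  tall <- list()
  for (f in perims$fires) {
    xy <- frame_coords(f$frame, f$ids)
    idx <- frame_index(landcover$frame, xy$x, xy$y)
    if (any(is.na(idx)))
      stop("fire(s) outside land-cover raster: ", f$fire_id)
    cls <- landcover$classes[idx]
    reg <- if (is.null(regions)) "all" else unname(regions[as.character(f$fire_id)])
    tall[[length(tall) + 1]] <- data.frame(
      region = reg, class = cn[cls],
      area_ha = rep(f$frame$res^2 / 1e4, length(cls)))
  }
  tt <- do.call(rbind, tall)
  agg <- stats::aggregate(area_ha ~ region + class, tt, sum)
  regs <- sort(unique(agg$region))
  fuel <- setdiff(cn, exclude)
  prop <- matrix(0, length(regs), length(fuel),
                 dimnames = list(regs, fuel))
  excl <- matrix(0, length(regs), length(exclude),
                 dimnames = list(regs, exclude))
  for (i in seq_len(nrow(agg))) {
    r <- agg$region[i]; cl <- agg$class[i]
    if (cl %in% fuel) prop[r, cl] <- agg$area_ha[i]
    else excl[r, cl] <- agg$area_ha[i]
  }
  area <- as.data.frame(prop)
  prop <- prop / rowSums(prop)
  list(proportions = as.data.frame(prop), excluded = as.data.frame(excl),
       area_ha = area)
}
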