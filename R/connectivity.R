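#' Connectivity parameters
#'
#' @param proximity_threshold_px Boundary-to-boundary distance (px) below
#'   which two somas are considered connected; 10 px is the published halo
#'   threshold for phase-contrast images at this magnification.
#' @param exclude_bright Whether [auto_exclude_bright()] removes somas sitting
#'   on very bright (assumed dead) areas.
#' @param bright_floor Fraction of the image maximum at or above which a
#'   soma's centroid pixel marks it as a dead cell.
#' @return A list of class `connectivity_params`.
#' @export
connectivity_params <- function(proximity_threshold_px = 10,
                                exclude_bright = TRUE,
                                bright_floor = 0.95) {
  stopifnot(
    proximity_threshold_px > 0,
    bright_floor > 0, bright_floor <= 1
  )
  structure(
    list(
      proximity_threshold_px = proximity_threshold_px,
      exclude_bright = exclude_bright,
      bright_floor = bright_floor
    ),
    class = "connectivity_params"
  )
}

#' Annotated soma set
#'
#' Container for manually annotated somas in one phase-contrast field:
#' centroids, boundary radii, an exclusion flag (dead cells, aggregates), and
#' optional dendrite links between soma ids. `grid_cell` labels the 500-um
#' relocation-grid square, `time_point_h` the imaging time in hours (the
#' study design used 0, 2, 4, 6, 24 h) and `group` the treatment arm.
#'
#' @param somas `data.frame` with columns `id`, `row`, `col`, `radius` and
#'   optionally `excluded` (default `FALSE`).
#' @param links Optional `data.frame` with columns `id_a`, `id_b` listing
#'   annotated dendrite connections; ids must exist in `somas`.
#' @param grid_cell,time_point_h,group Optional field metadata.
#' @return An object of class `soma_set`.
#' @export
soma_set <- function(somas, links = NULL, grid_cell = NA_character_,
                     time_point_h = NA_real_, group = NA_character_) {
  stopifnot(
    is.data.frame(somas),
    all(c("id", "row", "col", "radius") %in% names(somas))
  )
  if (anyDuplicated(somas$id)) {
    stop("soma ids must be unique")
  }
  if (is.null(somas$excluded)) {
    somas$excluded <- FALSE
  }
  stopifnot(all(somas$radius >= 0))
  if (!is.null(links) && nrow(links) > 0) {
    stopifnot(all(c("id_a", "id_b") %in% names(links)))
    unknown <- setdiff(c(links$id_a, links$id_b), somas$id)
    if (length(unknown)) {
      stop("links reference unknown soma ids: ", paste(unknown, collapse = ", "))
    }
  } else {
    links <- data.frame(id_a = integer(), id_b = integer())
  }
  structure(
    list(
      somas = somas, links = links, grid_cell = grid_cell,
      time_point_h = time_point_h, group = group
    ),
    class = "soma_set"
  )
}

#' @export
print.soma_set <- function(x, ...) {
  cat(sprintf(
    "<soma_set> %d somas (%d excluded), %d dendrite links%s\n",
    nrow(x$somas), sum(x$somas$excluded), nrow(x$links),
    if (!is.na(x$time_point_h)) sprintf(", t = %g h", x$time_point_h) else ""
  ))
  invisible(x)
}

#' Read soma annotations from CSV
#'
#' Soma CSV columns: `id,row,col,radius[,excluded]`; links CSV columns:
#' `id_a,id_b`.
#'
#' @param soma_csv Path to the soma annotation table.
#' @param links_csv Optional path to the dendrite-link table.
#' @inheritParams soma_set
#' @return A [soma_set()].
#' @export
read_soma_annotations <- function(soma_csv, links_csv = NULL,
                                  grid_cell = NA_character_,
                                  time_point_h = NA_real_,
                                  group = NA_character_) {
  somas <- utils::read.csv(soma_csv, stringsAsFactors = FALSE)
  links <- if (!is.null(links_csv)) {
    utils::read.csv(links_csv, stringsAsFactors = FALSE)
  }
  soma_set(somas, links,
    grid_cell = grid_cell,
    time_point_h = time_point_h, group = group
  )
}

#' Classify somas as connected or isolated
#'
#' Excluded somas are dropped first. A soma is *connected* when it appears in
#' at least one dendrite link, or when its boundary-to-boundary distance
#' (centroid distance minus both radii) to some other non-excluded soma is
#' below the proximity threshold; otherwise it is *isolated*. The distance is
#' boundary-referenced because the 10-px rule describes adjacent somas
#' sharing a phase-contrast halo; centroid distance would conflate soma size
#' with proximity. Connectivity is pairwise, not transitive. Links that
#' reference excluded somas are ignored with a warning.
#'
#' @param annotations A [soma_set()].
#' @param params A [connectivity_params()].
#' @return `data.frame` with columns `id`, `status`
#'   (`"connected"`/`"isolated"`).
#' @export
soma_status <- function(annotations, params = connectivity_params()) {
  stopifnot(inherits(annotations, "soma_set"))
  s <- annotations$somas[!annotations$somas$excluded, , drop = FALSE]
  links <- annotations$links
  if (nrow(links) > 0) {
    bad <- !(links$id_a %in% s$id) | !(links$id_b %in% s$id)
    if (any(bad)) {
      warning("ignoring ", sum(bad), " dendrite link(s) to excluded somas")
      links <- links[!bad, , drop = FALSE]
    }
  }
  n <- nrow(s)
  if (n == 0L) {
    return(data.frame(id = integer(), status = character()))
  }
  near <- rep(FALSE, n)
  if (n >= 2L) {
    d <- as.matrix(stats::dist(cbind(s$row, s$col)))
    gap <- d - outer(s$radius, s$radius, "+")
    diag(gap) <- Inf
    near <- apply(gap < params$proximity_threshold_px, 1L, any)
  }
  linked <- s$id %in% c(links$id_a, links$id_b)
  data.frame(
    id = s$id,
    status = ifelse(near | linked, "connected", "isolated"),
    stringsAsFactors = FALSE
  )
}

#' Total/isolated connectivity ratio
#'
#' The field-level metric: number of (non-excluded) somas divided by the
#' number of isolated somas. Higher values mean a more connected field; the
#' ratio is 1 when every soma is isolated and undefined (flagged, `NA`) when
#' no soma is isolated.
#'
#' @param statuses Status table from [soma_status()].
#' @return A list of class `connectivity_result` with `n_total`,
#'   `n_isolated`, `ratio` and `undefined` (logical).
#' @export
connectivity_ratio <- function(statuses) {
  n_total <- nrow(statuses)
  if (n_total == 0L) {
    stop("empty annotation set: no somas to summarize")
  }
  n_isolated <- sum(statuses$status == "isolated")
  undefined <- n_isolated == 0L
  structure(
    list(
      n_total = n_total,
      n_isolated = n_isolated,
      ratio = if (undefined) NA_real_ else n_total / n_isolated,
      undefined = undefined,
      statuses = statuses
    ),
    class = "connectivity_result"
  )
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf(
    "<connectivity_result> %d somas, %d isolated, ratio = %s\n",
    x$n_total, x$n_isolated,
    if (x$undefined) "undefined (fully connected)" else format(x$ratio, digits = 4)
  ))
  invisible(x)
}

#' Flag somas on very bright (dead-cell) areas as excluded
#'
#' Somas whose centroid pixel intensity is at or above
#' `bright_floor * max(image)` are marked excluded; very bright areas in
#' phase contrast are assumed to be dead cells and are omitted from the
#' connectivity analysis. With `bright_floor = 1` only exactly-maximal pixels
#' qualify.
#'
#' @param image Phase-contrast raster co-registered with the annotations.
#' @param annotations A [soma_set()].
#' @param params A [connectivity_params()]; when `exclude_bright` is `FALSE`
#'   the set is returned unchanged.
#' @return The `soma_set` with updated `excluded` flags.
#' @export
auto_exclude_bright <- function(image, annotations,
                                params = connectivity_params()) {
  stopifnot(inherits(annotations, "soma_set"))
  if (!params$exclude_bright) {
    return(annotations)
  }
  px <- as_raster(image)
  s <- annotations$somas
  ri <- pmin(pmax(as.integer(round_half_away(s$row)), 1L), nrow(px))
  ci <- pmin(pmax(as.integer(round_half_away(s$col)), 1L), ncol(px))
  bright <- px[cbind(ri, ci)] >= params$bright_floor * max(px)
  annotations$somas$excluded <- s$excluded | bright
  annotations
}

#' Compare connectivity ratios between groups over time
#'
#' For each time point, computes the mean ratio per group, the percent change
#' of treated relative to control (`100 * (control - treated) / control`) and
#' a two-sided two-sample Student's t-test p-value (pooled variance by
#' default, see [ttest_two_sample()]). Cells with fewer than 2 replicates in
#' either group get `NA` p-values and are flagged.
#'
#' @param ratios `data.frame` with columns `group` (`"control"`/`"treated"`),
#'   `time_point_h` and `ratio` (one row per field replicate).
#' @param welch Use the Welch unequal-variance t-test instead of the pooled
#'   Student form.
#' @return `data.frame` of class `connectivity_comparison`, one row per time
#'   point: group means and ns, `percent_change`, `t`, `p`, `flag`.
#' @export
compare_groups <- function(ratios, welch = FALSE) {
  stopifnot(all(c("group", "time_point_h", "ratio") %in% names(ratios)))
  bad_groups <- setdiff(unique(ratios$group), c("control", "treated"))
  if (length(bad_groups)) {
    stop("unknown group label(s): ", paste(bad_groups, collapse = ", "))
  }
  tps <- sort(unique(ratios$time_point_h))
  rows <- lapply(tps, function(tp) {
    ctl <- ratios$ratio[ratios$group == "control" & ratios$time_point_h == tp]
    trt <- ratios$ratio[ratios$group == "treated" & ratios$time_point_h == tp]
    ctl <- ctl[is.finite(ctl)]
    trt <- trt[is.finite(trt)]
    mc <- mean(ctl)
    mt <- mean(trt)
    pc <- 100 * (mc - mt) / mc
    if (length(ctl) >= 2 && length(trt) >= 2) {
      tt <- ttest_two_sample(ctl, trt, welch = welch)
      tstat <- tt$t
      p <- tt$p
      flag <- tt$flag
    } else {
      tstat <- NA_real_
      p <- NA_real_
      flag <- "insufficient replicates"
    }
    data.frame(
      time_point_h = tp,
      n_control = length(ctl), n_treated = length(trt),
      mean_control = mc, mean_treated = mt,
      percent_change = pc, t = tstat, p = p,
      flag = if (is.na(flag)) "" else flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("connectivity_comparison", class(out))
  out
}
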