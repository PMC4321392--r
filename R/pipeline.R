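#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sample t-test with a two-sided p-value from
#' the t distribution on `n_a + n_b - 2` degrees of freedom (`welch = TRUE`
#' switches to the unequal-variance Welch form). Degenerate zero-variance
#' input, on which `stats::t.test()` errors, is resolved explicitly: equal
#' means give `t = 0, p = 1`; unequal means give `p = 0` with a flag.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2, all finite.
#' @param welch Use Welch's unequal-variance form.
#' @return List with `t`, `df`, `p`, and `flag` (`NA` unless degenerate).
#' @export
ttest_two_sample <- function(group_a, group_b, welch = FALSE) {
  stopifnot(
    length(group_a) >= 2, length(group_b) >= 2,
    all(is.finite(group_a)), all(is.finite(group_b))
  )
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(
        t = 0, df = length(group_a) + length(group_b) - 2L,
        p = 1, flag = "zero variance, equal means"
      ))
    }
    return(list(
      t = sign(mean(group_a) - mean(group_b)) * Inf,
      df = length(group_a) + length(group_b) - 2L,
      p = 0, flag = "zero variance, separated means"
    ))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, flag = NA_character_
  )
}

#' Run the full arrangement-quantification pipeline over an image manifest
#'
#' For each manifest row: loads the channel images, standardizes them to the
#' canonical 600 x 600 geometry, computes the per-channel NCF, detects and
#' classifies nuclei, derives the coverage masks and the area/density
#' summary, and (when soma annotation CSVs are listed) the connectivity
#' ratio. Per-image failures are warned about and skipped; the run errors
#' only if every image fails. Writes one CSV per stage plus a JSON run
#' manifest (parameters, seed, package version) to `out_dir`; outputs are
#' deterministic given the same manifest and seed.
#'
#' @param manifest `data.frame` with columns `image_id`, `dapi`, `green`,
#'   `red` (file paths; `green`/`red` may be `NA` for NCF-only runs) and
#'   optionally `group`, `time_point_h`, `soma_csv`, `links_csv`.
#' @param out_dir Output directory, created if needed.
#' @param nuclei_par,area_par,conn_par Parameter blocks.
#' @param seed Recorded in the run manifest and set before processing (the
#'   analysis itself is deterministic; the seed matters only if stochastic
#'   generators feed the run).
#' @return Invisibly, a list with data.frames `ncf`, `nuclei`, `summary`,
#'   `connectivity` (NULL when no annotations) and the vector of written
#'   paths.
#' @export
run_pipeline <- function(manifest, out_dir,
                         nuclei_par = nuclei_params(),
                         area_par = area_params(),
                         conn_par = connectivity_params(),
                         seed = NULL) {
  stopifnot(
    is.data.frame(manifest), nrow(manifest) >= 1,
    all(c("image_id", "dapi") %in% names(manifest))
  )
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ncf_rows <- list()
  nuc_rows <- list()
  sum_rows <- list()
  conn_rows <- list()
  n_ok <- 0L
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    res <- tryCatch(
      {
        chans <- list(nuclei = load_channel(m$dapi, role = "nuclei"))
        has_gr <- !is.null(m$green) && !is.na(m$green) &&
          !is.null(m$red) && !is.na(m$red)
        if (has_gr) {
          chans$neuron <- load_channel(m$green, role = "neuron")
          chans$astrocyte <- load_channel(m$red, role = "astrocyte")
        }
        img <- standardize_image(lapply(chans, function(x) x$pixels))
        ncfs <- ncf_per_channel(img)
        ncf_df <- data.frame(
          image_id = m$image_id,
          channel = names(ncfs),
          f_bar_log = vapply(ncfs, `[[`, numeric(1), "f_bar_log"),
          ncf = vapply(ncfs, `[[`, numeric(1), "ncf"),
          row.names = NULL, stringsAsFactors = FALSE
        )
        recs <- detect_nuclei(img$channels$nuclei, nuclei_par)
        summ_df <- NULL
        if (has_gr) {
          gch <- img$channels$neuron
          rch <- img$channels$astrocyte
          recs <- classify_nuclei(recs, gch, rch)
          summ <- summarize_area_density(
            recs,
            neuron_mask(gch, rch, area_par),
            astrocyte_mask(rch, gch, area_par),
            pixel_scale = img$pixel_scale
          )
          summ_df <- data.frame(
            image_id = m$image_id,
            n_nuclei = nrow(recs),
            n_neurons = summ$n_neurons, n_glia = summ$n_glia,
            neuron_area_px = summ$neuron_area_px,
            glia_area_px = summ$glia_area_px,
            mean_neuron_area_um2 = summ$mean_neuron_area_um2,
            mean_glia_area_um2 = summ$mean_glia_area_um2,
            neuron_density_mm2 = summ$neuron_density_mm2,
            glia_density_mm2 = summ$glia_density_mm2,
            neuron_glia_ratio = summ$neuron_glia_ratio,
            undefined = paste(summ$undefined, collapse = ";"),
            stringsAsFactors = FALSE
          )
        }
        conn_df <- NULL
        if (!is.null(m$soma_csv) && !is.na(m$soma_csv)) {
          links_csv <- if (!is.null(m$links_csv) && !is.na(m$links_csv)) m$links_csv
          ann <- read_soma_annotations(
            m$soma_csv, links_csv,
            time_point_h = if (!is.null(m$time_point_h)) m$time_point_h else NA_real_,
            group = if (!is.null(m$group)) m$group else NA_character_
          )
          cres <- connectivity_ratio(soma_status(ann, conn_par))
          conn_df <- data.frame(
            image_id = m$image_id,
            group = ann$group, time_point_h = ann$time_point_h,
            n_total = cres$n_total, n_isolated = cres$n_isolated,
            ratio = cres$ratio,
            undefined = cres$undefined,
            stringsAsFactors = FALSE
          )
        }
        nuc_df <- if (nrow(recs)) cbind(image_id = m$image_id, recs) else NULL
        list(ncf = ncf_df, nuclei = nuc_df, summary = summ_df, conn = conn_df)
      },
      error = function(e) {
        warning(
          "skipping image '", m$image_id, "': ", conditionMessage(e),
          call. = FALSE
        )
        NULL
      }
    )
    if (!is.null(res)) {
      n_ok <- n_ok + 1L
      ncf_rows[[length(ncf_rows) + 1L]] <- res$ncf
      if (!is.null(res$nuclei)) nuc_rows[[length(nuc_rows) + 1L]] <- res$nuclei
      if (!is.null(res$summary)) sum_rows[[length(sum_rows) + 1L]] <- res$summary
      if (!is.null(res$conn)) conn_rows[[length(conn_rows) + 1L]] <- res$conn
    }
  }
  if (n_ok == 0L) {
    stop("all ", nrow(manifest), " manifest images failed to process")
  }
  bind <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  out <- list(
    ncf = bind(ncf_rows), nuclei = bind(nuc_rows),
    summary = bind(sum_rows), connectivity = bind(conn_rows)
  )
  paths <- c()
  for (nm in c("ncf", "nuclei", "summary", "connectivity")) {
    if (!is.null(out[[nm]])) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(out[[nm]], p, row.names = FALSE)
      paths[nm] <- p
    }
  }
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(
    list(
      package = "assemblyscope",
      version = as.character(utils::packageVersion("assemblyscope")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      n_images = nrow(manifest),
      n_processed = n_ok,
      parameters = list(
        nuclei = unclass(nuclei_par),
        area = unclass(area_par),
        connectivity = unclass(conn_par)
      ),
      images = manifest$image_id
    ),
    manifest_path,
    auto_unbox = TRUE, null = "null", digits = NA
  )
  paths["manifest"] <- manifest_path
  out$paths <- paths
  invisible(out)
}
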