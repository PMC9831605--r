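# End-to-end orchestration: validate -> (optional) template injection ->
# coordinate fields -> warps -> surfaces -> subfields -> morphometry -> QC.
# Plus the Dice-based automated error flagging.

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)`.  Defined as 1 when both masks are empty
#' (logged via message).
#'
#' @param a,b logical arrays on the same grid
#' @return Dice coefficient in `[0, 1]`
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch between masks")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    message("dice: both masks empty; returning 1")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

#' Flag a segmentation by Dice overlap with a reference mask
#'
#' Subjects whose grey-matter segmentation overlaps a reference mask with a
#' Dice score strictly below the threshold (default 0.7) are flagged for
#' manual inspection.
#'
#' @param seg_gm logical array, the segmented GM mask
#' @param reference_mask logical array, the reference mask (same grid)
#' @param threshold flagging threshold in (0, 1)
#' @return object of class `qc_result` with fields `dice`, `flagged`,
#'   `threshold`
#' @export
flag_low_dice <- function(seg_gm, reference_mask, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  d <- dice(seg_gm, reference_mask)
  structure(list(dice = d, flagged = d < threshold, threshold = threshold),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> dice=", signif(x$dice, 4),
      if (x$flagged) " FLAGGED" else " ok",
      " (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param io_mode `"equivolume"` or `"laplace"` laminar depth
#' @param densities surface densities to generate
#' @param atlas a [subfield_atlas()]; default the schematic banded atlas
#' @param inject run template shape injection (requires `template`)
#' @param template a [template_shape()] (required when `inject = TRUE`;
#'   also provides the QC reference mask if none is given)
#' @param reference_mask optional logical array for QC Dice flagging
#' @param dice_flag_threshold QC flag threshold, strict `<`
#' @param subject subject identifier used in output filenames
#' @param seed seed threaded to any stochastic component
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(io_mode = "equivolume",
                            densities = c("0p5mm", "unfoldiso"),
                            atlas = make_schematic_atlas(),
                            inject = FALSE, template = NULL,
                            reference_mask = NULL,
                            dice_flag_threshold = 0.7,
                            subject = "01", seed = 1L) {
  if (dice_flag_threshold <= 0 || dice_flag_threshold >= 1)
    stop("dice_flag_threshold must be in (0,1)")
  if (inject && is.null(template)) stop("injection requires a template")
  structure(list(io_mode = io_mode, densities = densities, atlas = atlas,
                 inject = inject, template = template,
                 reference_mask = reference_mask,
                 dice_flag_threshold = dice_flag_threshold,
                 subject = subject, seed = as.integer(seed)),
            class = "pipeline_config")
}

bids_name <- function(subject, hemi, space, den, suffix)
  paste0("sub-", subject, "_hemi-", hemi,
         if (!is.null(space)) paste0("_space-", space),
         if (!is.null(den)) paste0("_den-", den), "_", suffix)

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full unfolding pipeline on a labelmap
#'
#' Executes validation, optional template shape injection, Laplace
#' coordinate fields, bidirectional warps, surfaces at the requested
#' densities (plus DG surfaces when DG fields are available), subfield
#' labelling, morphometry, and Dice-based QC, writing all artifacts under
#' `out_dir` with BIDS-derivatives style names.  Deterministic given the
#' configuration.  Any stage failure halts with the stage name; outputs of
#' completed stages are retained.
#'
#' @param lm a [tissue_labelmap()] (or path to one)
#' @param out_dir output directory
#' @param config a [pipeline_config()]
#' @return (invisibly) a list of in-memory results: fields, warps, surfaces,
#'   metrics, subfields, qc
#' @export
run_pipeline <- function(lm, out_dir, config = pipeline_config()) {
  if (is.character(lm)) lm <- read_labelmap(lm)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hemi <- lm$hemisphere
  sub <- config$subject
  nm <- function(space, den, suffix)
    file.path(out_dir, bids_name(sub, hemi, space, den, suffix))

  report <- pipeline_stage("validate", {
    r <- validate_labelmap(lm)
    if (length(r$missing_labels))
      stop("missing required labels: ", paste(r$missing_labels, collapse = ", "))
    r
  })

  dg_fields <- NULL
  if (config$inject) {
    injected <- pipeline_stage("inject", inject(config$template, lm))
    lm_work <- injected$labelmap
    dg_fields <- injected$dg_fields
    write_labelmap(lm_work, nm(NULL, NULL, "desc-injected_dseg.nii.gz"))
  } else {
    lm_work <- lm
  }

  fields <- pipeline_stage("fields",
    compute_coord_fields(lm_work, io_mode = config$io_mode))
  write_coord_fields(fields, lm_work, file.path(out_dir,
    bids_name(sub, hemi, NULL, NULL, "laplace")))

  spec <- unfolded_space_spec("hipp")
  warp_n2u <- pipeline_stage("warps", build_native_to_unfolded(fields, lm_work, spec))
  warp_u2n <- pipeline_stage("warps", build_unfolded_to_native(fields, lm_work, spec))
  write_itk_warp(warp_n2u, nm("unfolded", NULL, "xfm.nii.gz"))
  write_itk_warp(warp_u2n, nm("native", NULL, "xfm.nii.gz"))

  surfaces <- list(); metrics <- list()
  manifest <- character(0)
  for (den in config$densities) {
    layers <- pipeline_stage("surfaces", build_layer_surfaces(spec, warp_u2n, den))
    surfaces[[den]] <- layers
    for (ly in c("inner", "midthickness", "outer")) {
      pth <- nm("native", den, paste0(ly, ".surf.gii"))
      write_gifti_surface(layers[[ly]], pth)
      manifest <- c(manifest, pth)
    }
    mm <- pipeline_stage("morphometry", {
      th <- thickness(layers$inner, layers$outer)
      sm <- smooth_mesh(layers$midthickness)
      cu <- mean_curvature(sm)
      gy <- gyrification(layers$midthickness, layers$unfolded_midthickness)
      list(thickness = th, curvature = cu, gyrification = gy)
    })
    metrics[[den]] <- mm
    for (mn in names(mm)) {
      pth <- nm("native", den, paste0(mn, ".shape.gii"))
      write_gifti_metric(mm[[mn]], pth)
      manifest <- c(manifest, pth)
    }
  }

  subf <- pipeline_stage("subfields", {
    vol <- fill_volumetric_subfields(config$atlas, fields, lm_work)
    den0 <- config$densities[1]
    labs <- label_vertices(config$atlas, surfaces[[den0]]$midthickness)
    topo <- check_topology(labs, surfaces[[den0]]$midthickness,
                           label_names = c(config$atlas$label_names,
                                           DG = max(config$atlas$label_names) + 1L))
    list(volume = vol, vertex_labels = labs, topology = topo, density = den0)
  })
  write_labelmap(subf$volume, nm(NULL, NULL, "desc-subfields_dseg.nii.gz"))
  write_gifti_labels(subf$vertex_labels, config$atlas$label_names,
                     nm("native", subf$density, "subfields.label.gii"))

  # per-subfield aggregate morphometry CSV
  agg <- pipeline_stage("morphometry", {
    den0 <- config$densities[1]
    labs <- subf$vertex_labels
    rows <- list()
    for (mn in names(metrics[[den0]])) {
      vals <- metrics[[den0]][[mn]]$values
      for (lb in sort(unique(labs))) {
        sel <- labs == lb & is.finite(vals)
        rows[[length(rows) + 1]] <- data.frame(
          subject = sub, hemi = hemi, metric = mn,
          subfield = names(config$atlas$label_names)[
            match(lb, config$atlas$label_names)],
          mean = mean(vals[sel]), sd = stats::sd(vals[sel]), n = sum(sel))
      }
    }
    do.call(rbind, rows)
  })
  write.csv(agg, file.path(out_dir, paste0("sub-", sub, "_hemi-", hemi,
                                           "_morphometry.csv")),
            row.names = FALSE)

  qc <- pipeline_stage("qc", {
    ref <- config$reference_mask
    if (is.null(ref) && config$inject) {
      # registration-based reference: the injected (template-shaped) GM
      ref <- label_mask(lm_work, "GM")
    }
    if (is.null(ref) && !is.null(config$template))
      ref <- label_mask(config$template$labelmap, "GM")
    if (is.null(ref)) ref <- label_mask(lm_work, "GM")
    flag_low_dice(label_mask(lm, "GM"), ref, config$dice_flag_threshold)
  })

  results <- list(validation = report, labelmap = lm_work, fields = fields,
                  warp_n2u = warp_n2u, warp_u2n = warp_u2n,
                  surfaces = surfaces, metrics = metrics,
                  subfields = subf, dg_fields = dg_fields, qc = qc,
                  manifest = manifest, out_dir = out_dir,
                  config = config)
  qc_report(results, out_dir)
  invisible(results)
}

#' Write the QC report for a pipeline run
#'
#' Emits a machine-readable JSON summary and a plain-text (plus minimal
#' HTML) report: Dice score and flag status, coordinate field ranges,
#' thickness summary, and vertex counts per density.
#'
#' @param results the list returned by [run_pipeline()]
#' @param out_dir directory to write into
#' @return paths written, invisibly
#' @export
qc_report <- function(results, out_dir) {
  qc <- results$qc
  fields <- results$fields
  rng <- function(a) range(a[is.finite(a)])
  counts <- lapply(results$surfaces, function(s) nrow(s$midthickness$vertices))
  th <- tryCatch(results$metrics[[1]]$thickness$values, error = function(e) NULL)
  summary <- list(
    subject = results$config$subject,
    dice = qc$dice, flagged = qc$flagged, threshold = qc$threshold,
    field_ranges = list(ap = rng(fields$ap), pd = rng(fields$pd),
                        io = rng(fields$io)),
    thickness_mean = if (!is.null(th)) mean(th[is.finite(th)]) else NA,
    thickness_sd = if (!is.null(th)) stats::sd(th[is.finite(th)]) else NA,
    vertex_counts = counts,
    n_gm_voxels = sum(results$fields$domain_mask)
  )
  jpath <- file.path(out_dir, "qc.json")
  jsonlite::write_json(summary, jpath, auto_unbox = TRUE, digits = NA)
  lines <- c(
    if (qc$flagged) "*** FLAGGED FOR REVIEW: low Dice overlap ***" else
      "QC passed (not flagged)",
    sprintf("subject: %s  hemi: %s", results$config$subject,
            results$labelmap$hemisphere),
    sprintf("dice vs reference: %.4f (flag threshold %.2f)", qc$dice,
            qc$threshold),
    sprintf("GM voxels: %d", sum(results$fields$domain_mask)),
    sprintf("field ranges: AP [%.3f, %.3f]  PD [%.3f, %.3f]  IO [%.3f, %.3f]",
            rng(fields$ap)[1], rng(fields$ap)[2], rng(fields$pd)[1],
            rng(fields$pd)[2], rng(fields$io)[1], rng(fields$io)[2]),
    if (!is.null(th)) sprintf("thickness: mean %.3f mm, sd %.3f mm",
                              mean(th[is.finite(th)]), sd(th[is.finite(th)])),
    "vertex counts per density:",
    vapply(names(counts), function(d) sprintf("  %s: %d vertices", d,
                                              counts[[d]]), character(1))
  )
  tpath <- file.path(out_dir, "qc_report.txt")
  writeLines(lines, tpath)
  hpath <- file.path(out_dir, "qc_report.html")
  writeLines(c("<html><body><pre>", lines, "</pre></body></html>"), hpath)
  invisible(c(jpath, tpath, hpath))
}
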