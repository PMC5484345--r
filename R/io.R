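#' Read a delimited curve table
#'
#' Curve tables are plain delimited text with a header. The time column
#' must be named `time_s` or `time_min` — the name declares the unit, and
#' times are converted to the package's internal minutes on read. An
#' optional `ca_mM` column holds the arterial input; every remaining
#' column is treated as one tissue curve (voxel) in mM.
#'
#' @param path Path to a comma- or tab-delimited file.
#'
#' @return A list with `t` (minutes), `ca` (curve tibble or `NULL`) and
#'   `C` (named list of curve tibbles, one per tissue column).
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                          progress = FALSE)
  tcol <- intersect(c("time_s", "time_min"), names(df))
  if (length(tcol) != 1) {
    abort("curve table must declare its time unit via a single `time_s` or `time_min` column")
  }
  t <- df[[tcol]]
  if (tcol == "time_s") t <- t / 60
  if (anyNA(t)) abort(sprintf("missing time stamps at rows %s",
                              paste(which(is.na(t)), collapse = ", ")))
  if (any(diff(t) <= 0)) {
    abort(sprintf("time stamps not strictly increasing at row %d",
                  which(diff(t) <= 0)[1] + 1))
  }
  conc_cols <- setdiff(names(df), tcol)
  for (cc in conc_cols) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad)) {
      abort(sprintf("column `%s`: non-finite concentration at row %d", cc, bad[1]))
    }
  }
  ca <- NULL
  if ("ca_mM" %in% conc_cols) {
    ca <- curve_tbl(t, df$ca_mM)
    conc_cols <- setdiff(conc_cols, "ca_mM")
  }
  C <- setNames(purrr::map(conc_cols, ~ curve_tbl(t, df[[.x]])), conc_cols)
  list(t = t, ca = ca, C = C)
}

#' Write curves to a delimited table
#'
#' Inverse of [read_curves()]: time is written in the declared unit with
#' the matching column name (`time_s` or `time_min`).
#'
#' @param path Output path (CSV).
#' @param t Time stamps in minutes.
#' @param ca Optional arterial curve tibble (written as `ca_mM`).
#' @param C Named list of tissue curve tibbles (or a single curve tibble,
#'   written as `C_mM`).
#' @param unit Output time unit, `"s"` or `"min"`.
#' @return The path, invisibly.
#' @export
write_curves <- function(path, t, ca = NULL, C = list(), unit = c("s", "min")) {
  unit <- match.arg(unit)
  out <- tibble(!!paste0("time_", unit) := if (unit == "s") t * 60 else t)
  if (!is.null(ca)) out$ca_mM <- ca$conc
  if (is.data.frame(C)) C <- list(C_mM = C)
  for (nm in names(C)) out[[nm]] <- C[[nm]]$conc
  readr::write_csv(out, path)
  invisible(path)
}

#' Fit many tissue curves against one arterial input
#'
#' The table-level front end: fits every tissue curve with the requested
#' method(s) and returns one tidy row per (curve, method) with the kinetic
#' parameters, derived quantities, fit residual, solution category and QC
#' decision.
#'
#' @param C Named list of tissue curve tibbles (as from [read_curves()]),
#'   or a single curve tibble.
#' @param ca Arterial curve tibble on the same grid.
#' @param method `"lls"`, `"nlls"` or `"both"`.
#' @param n_baseline Number of leading baseline samples for QC (default:
#'   samples before the first nonzero AIF value, minimum 2).
#' @param nlls_cfg [nlls_config()] for the nonlinear fits.
#'
#' @return A tibble with columns `curve`, `method`, `fp`, `vp`, `ps`,
#'   `tp`, `e`, `ktrans`, `residual_l2`, `category`, `converged`, `qc`.
#' @export
#'
#' @examples
#' t <- seq(0, 4, by = 2 / 60)
#' ca <- parker_aif_curve(t)
#' C <- list(v1 = ctu_forward(ctu_params(0.23, 0.05, 0.02), ca))
#' fit_curves(C, ca, method = "lls")
fit_curves <- function(C, ca, method = c("lls", "nlls", "both"),
                       n_baseline = NULL, nlls_cfg = nlls_config()) {
  method <- match.arg(method)
  methods <- if (method == "both") c("lls", "nlls") else method
  if (is.data.frame(C)) C <- list(C_mM = C)
  if (is.null(n_baseline)) {
    n_baseline <- max(2L, sum(cumsum(ca$conc > 0) == 0))
  }
  purrr::imap(C, function(curve, nm) {
    purrr::map(methods, function(m) {
      fit <- if (m == "lls") fit_ctu_lls(curve, ca) else
        fit_ctu_nlls(curve, ca, nlls_cfg)
      qc <- classify_voxel(curve, ca, fit, n_baseline)
      tibble(curve = nm, method = m,
             fp = fit$params$fp, vp = fit$params$vp, ps = fit$params$ps,
             tp = fit$derived$tp, e = fit$derived$e,
             ktrans = fit$derived$ktrans,
             residual_l2 = fit$residual_l2, category = fit$category,
             converged = fit$converged, qc = qc$decision)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Write deterministic simulation fixtures
#'
#' Generates the three literature tissue presets as curve tables at
#' `dt = 2` s — one noiseless file and one noisy file per CNR in
#' `c(5, 10, 20)` — plus a small synthetic 4D volume bundle (NIfTI volume,
#' mask, frame times and AIF table) when the `RNifti` package is
#' available. Byte-identical output for a given seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param cnrs Noise levels to generate.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, cnrs = c(5, 10, 20)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  set.seed(seed)
  presets <- tissue_presets()
  for (i in seq_len(nrow(presets))) {
    cfg <- sim_config(presets$tissue[i], dt_s = 2, cnr = 10, seed = seed)
    nl <- sim_noiseless(cfg)
    ds_ca <- downsample_jitter(nl$ca, 2, t0_s = 0)
    ds_C <- downsample_jitter(nl$C, 2, t0_s = 0)
    f <- file.path(dir, sprintf("%s_noiseless_dt2s.csv", presets$tissue[i]))
    write_curves(f, ds_ca$t, ca = ds_ca, C = list(C_mM = ds_C), unit = "s")
    files <- c(files, f)
    for (cnr in cnrs) {
      sigma <- sigma_from_cnr(nl$C, cnr)
      f <- file.path(dir, sprintf("%s_cnr%g_dt2s.csv", presets$tissue[i], cnr))
      write_curves(f, ds_ca$t, ca = add_noise(ds_ca, sigma),
                   C = list(C_mM = add_noise(ds_C, sigma)), unit = "s")
      files <- c(files, f)
    }
  }
  if (requireNamespace("RNifti", quietly = TRUE)) {
    files <- c(files, write_synthetic_volume(dir))
  }
  invisible(files)
}

# small synthetic 4D bundle: 4 x 4 x 2 voxels, brain-like kinetics with
# mild spatial parameter variation, built from the session RNG
write_synthetic_volume <- function(dir) {
  cfg <- sim_config("brain", dt_s = 2, cnr = 20)
  nl <- sim_noiseless(cfg)
  ca <- downsample_jitter(nl$ca, 2, t0_s = 0)
  nt <- nrow(ca)
  dims <- c(4, 4, 2)
  vol <- array(0, c(dims, nt))
  mask <- array(0L, dims)
  sigma <- sigma_from_cnr(nl$C, 20)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    if (i + j > 3) {                       # corner voxels left unmasked
      mask[i, j, k] <- 1L
      p <- ctu_params(0.23 * runif(1, 0.8, 1.2), 0.05 * runif(1, 0.8, 1.2),
                      0.02 * runif(1, 0.8, 1.2))
      cv <- add_noise(downsample_jitter(ctu_forward(p, nl$ca), 2, t0_s = 0),
                      sigma)
      vol[i, j, k, ] <- cv$conc
    }
  }
  fvol <- file.path(dir, "synthetic_conc4d.nii.gz")
  fmask <- file.path(dir, "synthetic_mask.nii.gz")
  faif <- file.path(dir, "synthetic_aif.csv")
  RNifti::writeNifti(RNifti::asNifti(vol), fvol)
  RNifti::writeNifti(RNifti::asNifti(mask), fmask)
  write_curves(faif, ca$t, ca = ca, unit = "s")
  c(fvol, fmask, faif)
}

#' Fit a 4D concentration volume voxelwise
#'
#' Loops over masked voxels of a 4D concentration array, fits each with
#' [fit_curves()] and returns the tidy table plus one 3D map per kinetic
#' parameter.
#'
#' @param vol 4D numeric array (x, y, z, t) of concentrations in mM, or a
#'   path to a NIfTI file (requires `RNifti`).
#' @param mask 3D array (nonzero = fit this voxel), or a NIfTI path.
#' @param t Frame times in minutes.
#' @param ca Arterial curve tibble on the same grid.
#' @param method `"lls"`, `"nlls"` or `"both"`.
#' @param ... Passed to [fit_curves()].
#'
#' @return A list with `table` (tidy per-voxel results, including voxel
#'   indices) and `maps` (named list of 3D arrays: `fp`, `vp`, `ps`,
#'   `ktrans`, and an integer `qc` category map; `NA` outside the mask).
#'   An empty mask yields an empty table with a warning.
#' @export
fit_volume <- function(vol, mask, t, ca, method = "lls", ...) {
  if (is.character(vol)) vol <- as.array(RNifti::readNifti(vol))
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  stopifnot(length(dim(vol)) == 4, all(dim(vol)[1:3] == dim(mask)[1:3]))
  if (dim(vol)[4] != length(t)) abort("4th dimension must match length(t)")
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warn("mask is empty: nothing to fit")
    return(list(table = tibble(), maps = list()))
  }
  curves <- setNames(
    purrr::map(seq_len(nrow(idx)),
               ~ curve_tbl(t, vol[idx[.x, 1], idx[.x, 2], idx[.x, 3], ])),
    sprintf("v%03d", seq_len(nrow(idx))))
  tab <- fit_curves(curves, ca, method = method, ...)
  tab <- dplyr::bind_cols(
    tab,
    as_tibble(idx[rep(seq_len(nrow(idx)),
                      each = nrow(tab) / nrow(idx)), , drop = FALSE]))
  qc_levels <- c("included", "excluded_negative_vd", "excluded_flat",
                 "lls_vp_negative", "lls_E_negative", "lls_E_above_one")
  maps <- purrr::map(c(fp = "fp", vp = "vp", ps = "ps", ktrans = "ktrans"),
                     function(col) {
                       m <- array(NA_real_, dim(mask))
                       first <- tab[!duplicated(tab$curve), ]
                       m[as.matrix(first[, c("dim1", "dim2", "dim3")])] <- first[[col]]
                       m
                     })
  qc_map <- array(NA_integer_, dim(mask))
  first <- tab[!duplicated(tab$curve), ]
  qc_map[as.matrix(first[, c("dim1", "dim2", "dim3")])] <-
    match(first$qc, qc_levels)
  maps$qc <- qc_map
  list(table = tab, maps = maps)
}
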