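# Environmental layers: gridded rasters with a land/sea mask, the Turc
# moisture index, equal-width stratification and log-proportional stratified
# random sampling of sites.

#' Construct an environmental raster
#'
#' A minimal gridded layer: a numeric matrix of values, a logical land mask of
#' the same shape, and the cell resolution in km. Sea cells may carry `NA`.
#'
#' @param values numeric matrix (rows x cols).
#' @param land logical matrix of the same shape; `TRUE` = land.
#' @param res_km positive cell size in km.
#' @return object of class `env_raster`.
#' @export
env_raster <- function(values, land, res_km = 15) {
  values <- as.matrix(values)
  land <- as.matrix(land)
  if (!identical(dim(values), dim(land)))
    stop("'values' and 'land' must have identical dimensions")
  if (!is.logical(land)) stop("'land' must be logical")
  if (!is.numeric(res_km) || res_km <= 0) stop("'res_km' must be positive")
  structure(list(values = values, land = land, res_km = res_km),
            class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  cat(sprintf("<env_raster> %d x %d cells, %.1f km, %d land (%.0f%%)\n",
              nrow(x$values), ncol(x$values), x$res_km, sum(x$land),
              100 * mean(x$land)))
  v <- x$values[x$land]
  cat(sprintf("  land values: [%.4g, %.4g]\n", min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  invisible(x)
}

#' Monthly potential evapotranspiration (Turc equation)
#'
#' Classic monthly Turc form: `PET = k * T/(T+15) * (Rs + 50)` mm/month with
#' `k = 0.40` for 30/31-day months and `k = 0.37` for February, and a
#' no-evaporation floor of 0 for `T <= 0` degrees C.
#'
#' @param mean_temp_C monthly mean temperature, degrees C (> -15).
#' @param solar_rad monthly mean solar radiation, cal cm^-2 day^-1 (>= 0).
#' @param days_in_month 28/29 selects the February coefficient.
#' @param coef_standard,coef_february the Turc coefficients (exposed because
#'   the constant set varies slightly between sources).
#' @return PET in mm/month (vectorized).
#' @examples
#' turc_pet(20, 400, 30)  # 0.40 * (20/35) * 450 = 102.857...
#' @export
turc_pet <- function(mean_temp_C, solar_rad, days_in_month,
                     coef_standard = 0.40, coef_february = 0.37) {
  if (any(mean_temp_C <= -15)) stop("temperature must exceed -15 C (Turc denominator)")
  if (any(solar_rad < 0)) stop("solar radiation must be non-negative")
  k <- ifelse(days_in_month %in% c(28L, 29L), coef_february, coef_standard)
  pet <- k * (mean_temp_C / (mean_temp_C + 15)) * (solar_rad + 50)
  ifelse(mean_temp_C <= 0, 0, pet)
}

#' Summer moisture index
#'
#' Mean over the three warmest months (June, July, August) of monthly
#' precipitation minus Turc potential evapotranspiration, in mm. Negative
#' values indicate a water deficit.
#'
#' @param precip_jun_jul_aug numeric length-3, monthly precipitation (mm).
#' @param pet_jun_jul_aug numeric length-3, monthly PET (mm), e.g. from
#'   [turc_pet()].
#' @return moisture index in mm.
#' @export
moisture_index <- function(precip_jun_jul_aug, pet_jun_jul_aug) {
  if (length(precip_jun_jul_aug) != 3L || length(pet_jun_jul_aug) != 3L)
    stop("both inputs must have length 3 (June, July, August)")
  mean(precip_jun_jul_aug - pet_jun_jul_aug)
}

#' Cross two environmental layers into an equal-width stratification
#'
#' Each variable is divided into `k` equal-width classes spanning its observed
#' min-max over land cells (top class right-closed so the maximum belongs to
#' class `k - 1`), and the two classifications are crossed into at most `k^2`
#' strata with id `class1 * k + class2` (0-based).
#'
#' @param env1,env2 [env_raster()] layers of identical shape.
#' @param k integer >= 2 classes per variable (default 9, giving 81 strata).
#' @return object of class `stratification`: integer stratum matrix (`NA` off
#'   land), class index matrices, break vectors and `k`.
#' @export
stratify <- function(env1, env2, k = 9) {
  stopifnot(inherits(env1, "env_raster"), inherits(env2, "env_raster"))
  if (!identical(dim(env1$values), dim(env2$values)))
    stop("layer shapes differ")
  if (k < 2) stop("'k' must be >= 2")
  land <- env1$land & env2$land
  cls <- function(r) {
    v <- r$values
    ok <- land & is.finite(v)
    mn <- min(v[ok]); mx <- max(v[ok])
    if (mx <= mn) stop("variable is constant over land: zero-width classes")
    w <- (mx - mn) / k
    ci <- pmin(floor((v - mn) / w), k - 1)
    ci[!ok] <- NA
    list(class = ci, breaks = seq(mn, mx, length.out = k + 1))
  }
  c1 <- cls(env1); c2 <- cls(env2)
  stratum <- c1$class * k + c2$class
  structure(list(stratum = stratum, class1 = c1$class, class2 = c2$class,
                 breaks1 = c1$breaks, breaks2 = c2$breaks, k = as.integer(k),
                 land = land),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("<stratification> k = %d (%d possible strata), %d occupied\n",
              x$k, x$k^2, length(unique(stats::na.omit(c(x$stratum))))))
  invisible(x)
}

#' Environmental-space centers of strata
#'
#' Midpoints of the class intervals for every stratum id present in the layer.
#'
#' @param strata a [stratify()] result.
#' @return data.frame with `stratum`, `class1`, `class2`, `env1_center`,
#'   `env2_center`.
#' @export
stratum_centers <- function(strata) {
  k <- strata$k
  ids <- sort(unique(stats::na.omit(c(strata$stratum))))
  c1 <- ids %/% k
  c2 <- ids %% k
  mid <- function(br, ci) (br[ci + 1] + br[ci + 2]) / 2
  data.frame(stratum = ids, class1 = c1, class2 = c2,
             env1_center = mid(strata$breaks1, c1),
             env2_center = mid(strata$breaks2, c2))
}

# run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Log-proportional stratified random sampling of sites
#'
#' Allocates sample sites to strata proportionally to the log of the number of
#' eligible pixels per stratum: a stratum with `n_s` eligible (land, occupied)
#' pixels receives
#' `round(min_n + (max_n - min_n) * (ln n_s - ln n_min) / (ln n_max - ln n_min))`
#' sites, clipped to `[min_n, min(max_n, n_s)]`, so the rarest stratum gets
#' `min_n` and the largest gets `max_n`. Sites are drawn uniformly without
#' replacement within each stratum. Strata without occupied pixels get none.
#'
#' @param strata a [stratify()] result.
#' @param occupancy numeric matrix of per-cell species counts (same shape as
#'   the stratification); a cell is eligible if its count is >= 1.
#' @param env1,env2 the [env_raster()] layers (per-site values are recorded).
#' @param min_n,max_n allocation endpoints (defaults 1 and 10).
#' @param seed integer seed fixing the random draw.
#' @return data.frame of class `sample_sites`: `site_id`, `row`, `col`
#'   (0-based), `stratum`, `env1`, `env2`.
#' @export
allocate_samples <- function(strata, occupancy, env1, env2,
                             min_n = 1, max_n = 10, seed = 1) {
  stopifnot(inherits(strata, "stratification"))
  occupancy <- as.matrix(occupancy)
  if (!identical(dim(occupancy), dim(strata$stratum)))
    stop("'occupancy' shape must match the stratification")
  if (min_n < 1 || max_n < min_n) stop("need max_n >= min_n >= 1")
  eligible <- strata$land & !is.na(strata$stratum) & occupancy >= 1
  if (!any(eligible)) stop("no eligible (occupied land) pixels in any stratum")
  cells <- which(eligible)                       # linear (column-major) indices
  strat_of <- strata$stratum[cells]
  n_s <- table(strat_of)
  n_min <- min(n_s); n_max <- max(n_s)
  target <- function(ns) {
    t_s <- if (n_max == n_min) max_n
           else min_n + (max_n - min_n) * (log(ns) - log(n_min)) /
                        (log(n_max) - log(n_min))
    pmin(pmax(round(t_s), min_n), pmin(max_n, ns))
  }
  nr <- nrow(occupancy)
  picks <- .with_seed(seed, {
    unlist(lapply(names(n_s), function(s) {
      pool <- cells[strat_of == as.integer(s)]
      t_s <- target(as.integer(n_s[[s]]))
      if (length(pool) == 1L) pool else sample(pool, t_s)
    }), use.names = FALSE)
  })
  picks <- sort(picks)
  row0 <- (picks - 1L) %% nr
  col0 <- (picks - 1L) %/% nr
  out <- data.frame(site_id = seq_along(picks), row = row0, col = col0,
                    stratum = strata$stratum[picks],
                    env1 = env1$values[picks], env2 = env2$values[picks])
  class(out) <- c("sample_sites", "data.frame")
  out
}

#' Read an ESRI ASCII grid
#'
#' Minimal reader for the plain-text `.asc` format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `nodata_value` header followed by
#' rows of values, top row first). `nodata` cells become `NA` and are marked
#' sea in the returned raster's land mask.
#'
#' @param path file path.
#' @param res_km resolution to record; defaults to the header `cellsize`.
#' @return an [env_raster()].
#' @export
read_ascii_grid <- function(path, res_km = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  land <- m != nodata
  m[!land] <- NA
  env_raster(m, land, res_km = if (is.null(res_km)) hdr$cellsize else res_km)
}

#' Write an [env_raster()] as an ESRI ASCII grid
#'
#' @param raster an [env_raster()].
#' @param path output file path.
#' @param nodata value written for sea/`NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  v <- raster$values
  v[!raster$land | is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %g", raster$res_km),
           sprintf("nodata_value %g", nodata))
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
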