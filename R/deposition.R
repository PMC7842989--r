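#' Synthetic deposition configuration
#'
#' Deposition is generative rather than mechanistic: the three-dimensional
#' impaction physics happens upstream of this package, so droplet streams
#' are assigned positions from size-class-specific mixtures of 2-D Gaussian
#' hot-spots anchored to named regions. Large droplets (> 60 um) impact a
#' band across the posterior vestibule, anterior septum and the middle
#' turbinate tip; droplets near 20 um favour the anterior main passage;
#' droplets near 30 um the ostium vicinity; only small droplets (< 20 um)
#' reach the nasopharynx tail.
#'
#' Droplet mass is split across three macro-buckets -- vestibule, main
#' cavity (main passage + septum + olfactory) and nasopharynx -- and the
#' per-class bucket probabilities are rescaled once at build time
#' (iterative proportional fitting) so the expected regional mass split
#' equals `target_split`.
#'
#' @param target_split Named target mass split in percent over
#'   `vestibule`, `main`, `nasopharynx` (defaults 79.8 / 19.0 / 1.2).
#' @param chamber Chamber receiving the spray (default `"right"`).
#' @param hotspots Optional data.frame overriding the default anchors:
#'   columns `name`, `bucket`, `x_mm`, `y_mm`, `sd_mm`, `w_large`,
#'   `w_medium`, `w_small`.
#' @param base_bucket_weights 3 x 3 matrix of pre-scaling bucket weights,
#'   rows = size classes (`large`, `medium`, `small`), columns = buckets
#'   (`vestibule`, `main`, `nasopharynx`). Structural zeros are preserved
#'   by the rescaling.
#' @param class_breaks_um Diameter breaks separating small/medium/large
#'   (default `c(20, 60)`).
#' @return An object of class `mc_deposition_config`.
#' @export
deposition_config <- function(target_split = c(vestibule = 79.8, main = 19.0,
                                               nasopharynx = 1.2),
                              chamber = "right",
                              hotspots = NULL,
                              base_bucket_weights = NULL,
                              class_breaks_um = c(20, 60)) {
  if (any(target_split < 0) || abs(sum(target_split) - 100) > 1e-6) {
    stop("target split must be non-negative and sum to 100%", call. = FALSE)
  }
  if (is.null(base_bucket_weights)) {
    base_bucket_weights <- rbind(
      large = c(vestibule = 0.80, main = 0.20, nasopharynx = 0),
      medium = c(vestibule = 0.75, main = 0.25, nasopharynx = 0),
      small = c(vestibule = 0.20, main = 0.30, nasopharynx = 0.50)
    )
  }
  if (any(base_bucket_weights < 0)) {
    stop("bucket weights must be non-negative", call. = FALSE)
  }
  if (is.null(rownames(base_bucket_weights))) {
    rownames(base_bucket_weights) <- c("large", "medium", "small")
  }
  if (is.null(colnames(base_bucket_weights))) {
    colnames(base_bucket_weights) <- c("vestibule", "main", "nasopharynx")
  }
  structure(
    list(target_split = target_split, chamber = chamber, hotspots = hotspots,
         base_bucket_weights = base_bucket_weights,
         class_breaks_um = class_breaks_um),
    class = "mc_deposition_config"
  )
}

bucket_regions <- function(bucket) {
  switch(bucket,
         vestibule = "vestibule",
         main = c("main_passage", "septum", "olfactory"),
         nasopharynx = "nasopharynx",
         stop("unknown bucket ", bucket, call. = FALSE))
}

size_class <- function(d_um, breaks = c(20, 60)) {
  ifelse(d_um < breaks[1], "small", ifelse(d_um > breaks[2], "large", "medium"))
}

default_hotspots <- function(domain, chamber = "right") {
  res <- domain$res_mm
  m <- domain$rows_per_chamber
  cfg <- domain$config
  vest_x <- if (!is.null(cfg)) cfg$vestibule_length_mm else domain$nx * res * 0.15
  len <- domain$nx * res
  # y offsets measured from the chamber's septal (mid-line) edge outwards
  ch_y <- function(off_frac) {
    if (!domain$two_chambers) {
      off_frac * m * res
    } else if (chamber == "right") {
      (m + off_frac * m) * res
    } else {
      (m - off_frac * m) * res
    }
  }
  naso_y <- domain$ny * res / 2
  df <- data.frame(
    name = c("vestibule_posterior", "vestibule_lateral", "septum_anterior",
             "turbinate_tip", "main_anterior", "ostium_vicinity", "naso_tail"),
    bucket = c("vestibule", "vestibule", "main", "main", "main", "main",
               "nasopharynx"),
    x_mm = c(vest_x - 8, vest_x - 10, vest_x + 9, vest_x + 16, vest_x + 7,
             (if (!is.null(cfg)) cfg$ostium_x_mm else len * 0.5), len * 0.92),
    y_mm = c(ch_y(0.42), ch_y(0.78), ch_y(0.12), ch_y(0.58), ch_y(0.55),
             ch_y(0.60), naso_y),
    sd_mm = c(4, 5, 5, 4, 6, 5, 8),
    w_large = c(1, 0, 0.45, 0.55, 0, 0, 0),
    w_medium = c(0.3, 0.7, 0.15, 0, 0.70, 0.15, 0),
    w_small = c(0, 1, 0, 0, 1, 0, 1),
    stringsAsFactors = FALSE
  )
  df
}

# per-class bucket probabilities rescaled so the expected mass split over
# buckets hits the target (iterative proportional fitting on the class
# marginals)
bucket_mix <- function(population, config) {
  classes <- c("large", "medium", "small")
  cls <- size_class(population$d_um, config$class_breaks_um)
  mass_c <- vapply(classes, function(k) sum(population$mass_fraction[cls == k]), 0)
  mass_c <- mass_c / sum(mass_c)
  target <- config$target_split / 100
  B <- config$base_bucket_weights[classes, names(target), drop = FALSE]
  lambda <- rep(1, length(target))
  q <- B
  for (it in seq_len(500)) {
    q <- sweep(B, 2, lambda, `*`)
    q <- q / rowSums(q)
    got <- as.numeric(mass_c %*% q)
    if (max(abs(got - target)) < 1e-12) break
    adj <- ifelse(got > 0, target / got, 1)
    lambda <- lambda * adj
  }
  got <- as.numeric(mass_c %*% q)
  if (max(abs(got - target)) > 1e-4) {
    warning("expected regional split differs from target by ",
            signif(max(abs(got - target)) * 100, 2), " percentage points")
  }
  rownames(q) <- classes
  q
}

#' Generate a synthetic deposition pattern
#'
#' Assigns every droplet stream of the population a deposition position
#' sampled from its size class's hot-spot mixture, truncated to the cells
#' of the hot-spot's macro-bucket; positions are snapped to their
#' containing grid cell. All streams deposit (100% deposition efficiency),
#' each carrying `mass_fraction / streams` of the normalised (1 kg) spray
#' mass. Reproducible under a fixed seed.
#'
#' @param population An [build_droplet_population()] result.
#' @param domain An `mc_domain`.
#' @param config An [deposition_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `mc_deposition`: a data.frame with columns
#'   `id`, `d_um`, `mass_kg`, `x_mm`, `y_mm`, `cell`, `region`, `time_s`.
#' @export
generate_deposition <- function(population, domain,
                                config = deposition_config(), seed = 1) {
  if (nrow(population) == 0) stop("empty droplet population", call. = FALSE)
  spots <- if (is.null(config$hotspots)) {
    default_hotspots(domain, config$chamber)
  } else {
    config$hotspots
  }
  chk <- locate_cells(domain, spots$x_mm, spots$y_mm)
  if (anyNA(chk)) {
    stop("hot-spot centred outside the domain: ",
         paste(spots$name[is.na(chk)], collapse = ", "), call. = FALSE)
  }
  q <- bucket_mix(population, config)
  set.seed(seed)

  streams <- rep(seq_len(nrow(population)), population$streams)
  d_um <- population$d_um[streams]
  mass <- (population$mass_fraction / population$streams)[streams]
  cls <- size_class(d_um, config$class_breaks_um)
  n <- length(streams)

  # sample bucket per stream from its class mixture
  buckets <- colnames(q)
  u <- stats::runif(n)
  cum <- t(apply(q, 1, cumsum))
  cum[, ncol(cum)] <- 1
  bucket <- buckets[max.col(cum[cls, , drop = FALSE] >= u, ties.method = "first")]

  # sample hot-spot within (class, bucket)
  wcol <- c(large = "w_large", medium = "w_medium", small = "w_small")
  spot_of <- integer(n)
  for (k in unique(cls)) {
    for (b in unique(bucket[cls == k])) {
      rows <- which(cls == k & bucket == b)
      cand <- which(spots$bucket == b & spots[[wcol[k]]] > 0)
      if (!length(cand)) cand <- which(spots$bucket == b)
      if (!length(cand)) {
        stop("no hot-spot available for bucket ", b, call. = FALSE)
      }
      w <- spots[[wcol[k]]][cand]
      if (sum(w) <= 0) w <- rep(1, length(cand))
      spot_of[rows] <- cand[sample.int(length(cand), length(rows),
                                       replace = TRUE, prob = w)]
    }
  }

  # rejection-sample Gaussian positions truncated to the bucket's regions
  cells <- domain$cells
  chamber_ok <- function(b) {
    if (b == "nasopharynx") rep(TRUE, nrow(cells))
    else cells$chamber == config$chamber | !domain$two_chambers
  }
  x <- numeric(n); y <- numeric(n); cell <- rep(NA_integer_, n)
  todo <- seq_len(n)
  for (try in seq_len(60)) {
    if (!length(todo)) break
    sp <- spot_of[todo]
    xt <- stats::rnorm(length(todo), spots$x_mm[sp], spots$sd_mm[sp])
    yt <- stats::rnorm(length(todo), spots$y_mm[sp], spots$sd_mm[sp])
    cid <- locate_cells(domain, xt, yt)
    ok <- !is.na(cid)
    if (any(ok)) {
      regs <- cells$region[cid[ok]]
      idx <- todo[ok]
      valid <- logical(length(idx))
      for (b in buckets) {
        sel <- bucket[idx] == b
        if (!any(sel)) next
        allowed <- bucket_regions(b)
        valid[sel] <- regs[sel] %in% allowed &
          chamber_ok(b)[cid[ok]][sel]
      }
      keep <- idx[valid]
      x[keep] <- xt[ok][valid]; y[keep] <- yt[ok][valid]
      cell[keep] <- cid[ok][valid]
      todo <- setdiff(todo, keep)
    }
  }
  if (length(todo)) {
    # fall back to the nearest admissible cell centre
    for (i in todo) {
      b <- bucket[i]
      adm <- which(cells$region %in% bucket_regions(b) & chamber_ok(b))
      if (!length(adm)) adm <- seq_len(nrow(cells))
      sp <- spot_of[i]
      d2 <- (cells$x_mm[adm] - spots$x_mm[sp])^2 +
        (cells$y_mm[adm] - spots$y_mm[sp])^2
      j <- adm[which.min(d2)]
      x[i] <- cells$x_mm[j]; y[i] <- cells$y_mm[j]; cell[i] <- j
    }
  }

  out <- data.frame(
    id = seq_len(n), d_um = d_um, mass_kg = mass,
    x_mm = x, y_mm = y, cell = cell,
    region = cells$region[cell], time_s = 0
  )
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("mc_deposition", "data.frame")
  out
}

#' Regional deposited mass fractions
#'
#' @param particles An `mc_deposition` (or compatible data.frame with
#'   `region` and `mass_kg`).
#' @param domain An `mc_domain` (regions with no deposits are reported as
#'   zero).
#' @return Data.frame with `region` and `mass_percent`, summing to 100.
#' @export
regional_mass_fractions <- function(particles, domain = NULL) {
  if (nrow(particles) == 0) stop("empty particle list", call. = FALSE)
  tot <- sum(particles$mass_kg)
  by_reg <- tapply(particles$mass_kg, particles$region, sum)
  regions <- if (!is.null(domain)) {
    unique(c(unique(domain$cells$region), names(by_reg)))
  } else {
    names(by_reg)
  }
  pct <- ifelse(regions %in% names(by_reg), by_reg[regions], 0) / tot * 100
  data.frame(region = regions, mass_percent = as.numeric(pct),
             stringsAsFactors = FALSE)
}

#' Write a deposition table to CSV
#'
#' @param particles An `mc_deposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deposition_csv <- function(particles, path) {
  utils::write.csv(
    particles[, c("id", "d_um", "mass_kg", "x_mm", "y_mm")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Load a deposition table
#'
#' Ingests externally computed deposition exports with columns `id`,
#' `d_um`, `mass_kg`, `x_mm`, `y_mm`. Rows outside the domain are dropped
#' with a warning; their indices are attached as attribute `"rejected"`.
#'
#' @param path CSV path.
#' @param domain An `mc_domain`.
#' @return An `mc_deposition`.
#' @export
load_deposition_csv <- function(path, domain) {
  df <- utils::read.csv(path)
  need <- c("id", "d_um", "mass_kg", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("deposition CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cell <- locate_cells(domain, df$x_mm, df$y_mm)
  rejected <- which(is.na(cell))
  if (length(rejected)) {
    warning("rejected ", length(rejected), " out-of-domain row(s): ",
            paste(utils::head(rejected, 20), collapse = ", "))
    df <- df[-rejected, , drop = FALSE]
    cell <- cell[-rejected]
  }
  out <- data.frame(
    id = df$id, d_um = df$d_um, mass_kg = df$mass_kg,
    x_mm = df$x_mm, y_mm = df$y_mm, cell = cell,
    region = domain$cells$region[cell], time_s = 0
  )
  attr(out, "rejected") <- rejected
  class(out) <- c("mc_deposition", "data.frame")
  out
}
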