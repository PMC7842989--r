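#' Anatomical region catalogue
#'
#' The unwrapped nasal-wall surface is partitioned into major anatomical
#' regions. The vestibule is squamous epithelium: it neither absorbs drug
#' solute nor produces mucus. The respiratory-epithelium regions (main
#' passage, septum, olfactory, nasopharynx, maxillary sinus) all absorb;
#' mucus is produced on the main cavity mucosa and, strongly, by the
#' maxillary sinuses whose output enters the main domain through the
#' ostium patches.
#'
#' @return A data.frame with columns `region`, `absorbing`,
#'   `mucus_producing`.
#' @export
region_specs <- function() {
  data.frame(
    region = c("vestibule", "main_passage", "septum", "olfactory",
               "maxillary_sinus", "nasopharynx", "ostium_patch"),
    absorbing = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    mucus_producing = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

region_names <- function() region_specs()$region

#' Default domain configuration
#'
#' Regional wall areas default to the reference geometry: per-chamber areas
#' (cm^2) for the vestibule, main passage, septum, olfactory region and
#' maxillary sinus, plus a single shared nasopharynx. The maxillary sinus
#' interiors are not meshed; they are represented by their ostium source
#' patches inside each chamber's main-passage band, and their configured
#' areas enter the bookkeeping only.
#'
#' The unwrapped plane is parametric: `x_mm` runs anterior (nostril) to
#' posterior (outlet), `y_mm` across the unwrapped circumference with the
#' two chambers stacked as independent strips that merge into one shared
#' nasopharynx strip. Per-cell areas are scaled per region so that the cell
#' sums reproduce the configured areas exactly; the plane is therefore not
#' isometric, exactly as a real unwrapped surface is not.
#'
#' @param areas_left,areas_right Named numeric vectors of per-chamber areas
#'   in cm^2 (`vestibule`, `main_passage`, `septum`, `olfactory`,
#'   `maxillary_sinus`). A zero area removes the region.
#' @param area_nasopharynx Area of the shared nasopharynx strip in cm^2.
#' @param resolution_mm Cell edge length of the structured grid in mm.
#' @param length_mm Total anterior-posterior extent of the unwrapped plane.
#' @param vestibule_length_mm Extent of the anterior vestibule band.
#' @param nasopharynx_length_mm Extent of the posterior shared strip.
#' @param chamber_width_mm Unwrapped circumferential width of one chamber.
#' @param septum_frac Fraction of each chamber's rows, adjacent to the
#'   shared mid-line, labelled septum.
#' @param olfactory_frac Fraction of each chamber's rows, along the outer
#'   edge (the unwrapped ceiling), labelled olfactory.
#' @param olfactory_x0_mm Anterior limit of the olfactory band.
#' @param ostium_x_mm,ostium_halfwidth_mm Centre and half-width of the
#'   square ostium source patch placed in each chamber's main-passage band.
#' @param naso_end_width_factor Metric width factor at the outlet edge; the
#'   factor decays linearly from 1 across the nasopharynx strip, emulating
#'   the rapidly shrinking circumference that accelerates the mucus.
#' @return A list of class `mc_domain_config`.
#' @export
domain_config <- function(areas_left = c(vestibule = 8.04, main_passage = 56.3,
                                         septum = 20.8, olfactory = 9.12,
                                         maxillary_sinus = 15.4),
                          areas_right = c(vestibule = 8.42, main_passage = 54.1,
                                          septum = 20.4, olfactory = 9.87,
                                          maxillary_sinus = 10.9),
                          area_nasopharynx = 11.7,
                          resolution_mm = 2,
                          length_mm = 85,
                          vestibule_length_mm = 13,
                          nasopharynx_length_mm = 13,
                          chamber_width_mm = 56,
                          septum_frac = 0.25,
                          olfactory_frac = 0.15,
                          olfactory_x0_mm = 42,
                          ostium_x_mm = 50,
                          ostium_halfwidth_mm = 2,
                          naso_end_width_factor = 0.4) {
  cfg <- list(
    areas_left = areas_left, areas_right = areas_right,
    area_nasopharynx = area_nasopharynx,
    resolution_mm = resolution_mm, length_mm = length_mm,
    vestibule_length_mm = vestibule_length_mm,
    nasopharynx_length_mm = nasopharynx_length_mm,
    chamber_width_mm = chamber_width_mm,
    septum_frac = septum_frac, olfactory_frac = olfactory_frac,
    olfactory_x0_mm = olfactory_x0_mm,
    ostium_x_mm = ostium_x_mm, ostium_halfwidth_mm = ostium_halfwidth_mm,
    naso_end_width_factor = naso_end_width_factor
  )
  validate_domain_config(cfg)
  class(cfg) <- "mc_domain_config"
  cfg
}

validate_domain_config <- function(cfg) {
  for (side in c("areas_left", "areas_right")) {
    a <- cfg[[side]]
    if (length(a) && (is.null(names(a)) || any(!names(a) %in% region_names()))) {
      stop("unknown region name in ", side, call. = FALSE)
    }
    if (any(a < 0)) stop("region areas must be non-negative", call. = FALSE)
  }
  if (cfg$area_nasopharynx < 0) stop("region areas must be non-negative", call. = FALSE)
  if (cfg$resolution_mm <= 0) stop("resolution must be positive", call. = FALSE)
  pos <- c(cfg$length_mm, cfg$chamber_width_mm)
  if (any(pos <= 0)) stop("domain dimensions must be positive", call. = FALSE)
  if (cfg$vestibule_length_mm < 0 || cfg$nasopharynx_length_mm < 0 ||
      cfg$vestibule_length_mm + cfg$nasopharynx_length_mm >= cfg$length_mm) {
    stop("vestibule and nasopharynx bands must fit inside the domain length",
         call. = FALSE)
  }
  if (cfg$naso_end_width_factor <= 0) {
    stop("width factor must stay positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Build a synthetic unwrapped nasal-wall surface
#'
#' Constructs a structured quadrilateral grid in the unwrapped plane: two
#' chamber strips (left below, right above the shared mid-line), each with
#' an anterior vestibule band, a septum band along the mid-line, an
#' olfactory band along the outer edge, main-passage cells elsewhere and an
#' ostium patch, merging into a single shared nasopharynx strip that ends
#' at the outlet edge. Per-cell areas are scaled per region and chamber so
#' that the summed areas equal the configured regional areas exactly.
#'
#' @param config A [domain_config()] object (or a list accepted by it).
#' @return An object of class `mc_domain` with elements `cells` (the cell
#'   table), `regions` (regional bookkeeping including unmeshed maxillary
#'   sinuses), grid metadata and the originating config.
#' @export
#' @examples
#' dom <- build_synthetic_domain(domain_config(resolution_mm = 4))
#' dom
build_synthetic_domain <- function(config = domain_config()) {
  if (!inherits(config, "mc_domain_config")) {
    config <- do.call(domain_config, config)
  }
  res <- config$resolution_mm
  nx <- max(1L, round(config$length_mm / res))
  m <- max(1L, round(config$chamber_width_mm / res))   # rows per chamber
  chambers_present <- c(sum(config$areas_left) > 0, sum(config$areas_right) > 0)
  if (!any(chambers_present)) stop("at least one chamber must have area", call. = FALSE)
  two <- all(chambers_present)
  ny <- if (two) 2L * m else m

  x_centres <- (seq_len(nx) - 0.5) * res
  y_centres <- (seq_len(ny) - 0.5) * res

  n_vest <- round(config$vestibule_length_mm / res)
  n_naso <- round(config$nasopharynx_length_mm / res)
  if (config$area_nasopharynx <= 0) n_naso <- 0L
  naso_x0 <- nx - n_naso          # columns > naso_x0 are nasopharynx
  n_sep <- round(config$septum_frac * m)
  n_olf <- round(config$olfactory_frac * m)

  grid <- expand.grid(iy = seq_len(ny), ix = seq_len(nx))
  ix <- grid$ix; iy <- grid$iy
  chamber <- if (two) ifelse(iy <= m, "left", "right") else
    if (chambers_present[1]) "left" else "right"
  # row index counted from the shared mid-line into each chamber
  row_in <- if (two) ifelse(iy <= m, m - iy + 1L, iy - m) else
    if (chambers_present[1]) m - iy + 1L else iy

  region <- rep("main_passage", length(ix))
  areas_of <- function(ch) if (ch == "left") config$areas_left else config$areas_right
  has <- function(ch, rg) {
    a <- areas_of(ch)
    !is.na(a[rg]) && isTRUE(a[rg] > 0)
  }
  sep_rows <- row_in <= n_sep
  olf_rows <- row_in > m - n_olf
  in_olf_x <- x_centres[ix] >= config$olfactory_x0_mm
  for (ch in c("left", "right")[chambers_present]) {
    sel <- chamber == ch
    if (has(ch, "septum")) region[sel & sep_rows] <- "septum"
    if (has(ch, "olfactory")) region[sel & olf_rows & in_olf_x] <- "olfactory"
    vest_sel <- sel & ix <= n_vest
    if (has(ch, "vestibule")) region[vest_sel] <- "vestibule"
  }
  if (n_naso > 0) region[ix > naso_x0] <- "nasopharynx"

  # ostium patches: square block inside each chamber's main-passage band
  is_ostium <- rep(FALSE, length(ix))
  for (ch in c("left", "right")[chambers_present]) {
    if (!has(ch, "maxillary_sinus")) next
    mid_row <- round(m * 0.6)     # between septum band and olfactory band
    oy <- if (!two) mid_row else if (ch == "left") m - mid_row + 1L else m + mid_row
    ox <- round(config$ostium_x_mm / res)
    hw <- max(0L, round(config$ostium_halfwidth_mm / res) - 1L)
    sel <- chamber == ch & abs(ix - ox) <= hw & abs(iy - oy) <= hw &
      region == "main_passage"
    if (!any(sel)) {
      sel <- chamber == ch & ix == ox & iy == oy & region == "main_passage"
    }
    is_ostium[sel] <- TRUE
  }

  is_outlet <- ix == nx

  # width factor: 1 in the chambers, linear decay across the nasopharynx
  width_factor <- rep(1, length(ix))
  if (n_naso > 0) {
    frac <- (x_centres[ix] - (naso_x0 * res)) / (n_naso * res)
    in_naso <- ix > naso_x0
    width_factor[in_naso] <- 1 + (config$naso_end_width_factor - 1) *
      pmin(pmax(frac[in_naso], 0), 1)
  }

  cells <- data.frame(
    cell = seq_along(ix), ix = ix, iy = iy,
    x_mm = x_centres[ix], y_mm = y_centres[iy],
    area_cm2 = NA_real_, region = region, chamber = chamber,
    width_factor = width_factor, is_outlet = is_outlet,
    is_ostium = is_ostium, stringsAsFactors = FALSE
  )
  if (n_naso > 0) cells$chamber[cells$region == "nasopharynx"] <- "shared"

  # per-(region, chamber) area scaling so cell sums match configured areas
  key <- paste(cells$region, cells$chamber)
  target <- c()
  for (ch in c("left", "right")[chambers_present]) {
    a <- areas_of(ch)
    for (rg in setdiff(names(a)[a > 0], "maxillary_sinus")) {
      target[paste(rg, ch)] <- a[[rg]]
    }
  }
  if (n_naso > 0) target["nasopharynx shared"] <- config$area_nasopharynx
  counts <- table(key)
  missing <- setdiff(names(target), names(counts))
  if (length(missing)) {
    stop("regions could not be tiled at this resolution (achievable area 0): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(counts), names(target))
  if (length(extra)) {
    stop("internal tiling produced unconfigured regions: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  cells$area_cm2 <- unname(target[key] / as.numeric(counts[key]))

  regions <- regional_bookkeeping(config, chambers_present)

  dom <- structure(
    list(
      cells = cells, regions = regions,
      nx = nx, ny = ny, res_mm = res,
      two_chambers = two, rows_per_chamber = m,
      naso_x0_col = naso_x0,
      index = matrix(match(paste(rep(seq_len(ny), nx), rep(seq_len(nx), each = ny)),
                           paste(cells$iy, cells$ix)),
                     nrow = ny, ncol = nx),
      config = config
    ),
    class = "mc_domain"
  )
  validate_domain(dom)
  dom
}

regional_bookkeeping <- function(config, chambers_present = c(TRUE, TRUE)) {
  specs <- region_specs()
  rows <- list()
  for (ch in c("left", "right")[chambers_present]) {
    a <- if (ch == "left") config$areas_left else config$areas_right
    for (rg in names(a)[a > 0]) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, chamber = ch, area_cm2 = a[[rg]],
        meshed = rg != "maxillary_sinus", stringsAsFactors = FALSE
      )
    }
  }
  if (config$area_nasopharynx > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      region = "nasopharynx", chamber = "shared",
      area_cm2 = config$area_nasopharynx, meshed = TRUE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$absorbing <- specs$absorbing[match(out$region, specs$region)]
  out$mucus_producing <- specs$mucus_producing[match(out$region, specs$region)]
  out
}

validate_domain <- function(dom) {
  cells <- dom$cells
  if (anyDuplicated(cells[, c("x_mm", "y_mm")])) {
    stop("duplicate cell coordinates", call. = FALSE)
  }
  if (any(cells$width_factor <= 0)) {
    stop("metric width factor must be positive everywhere", call. = FALSE)
  }
  if (any(!cells$region %in% region_names())) {
    stop("unknown region label in cell table", call. = FALSE)
  }
  if ("nasopharynx" %in% cells$region &&
      !all(cells$region[cells$is_outlet] == "nasopharynx")) {
    stop("outlet cells must belong to the nasopharynx", call. = FALSE)
  }
  meshed <- dom$regions[dom$regions$meshed, ]
  got <- tapply(cells$area_cm2, paste(cells$region, cells$chamber), sum)
  want <- stats::setNames(meshed$area_cm2, paste(meshed$region, meshed$chamber))
  rel <- abs(got[names(want)] - want) / want
  if (any(is.na(rel)) || any(rel > 0.005)) {
    stop("cell areas deviate from configured regional areas by more than 0.5%",
         call. = FALSE)
  }
  invisible(dom)
}

#' @export
print.mc_domain <- function(x, ...) {
  cat(sprintf(
    "Unwrapped nasal-wall domain: %d x %d grid (%.1f mm cells), %d cells\n",
    x$ny, x$nx, x$res_mm, nrow(x$cells)
  ))
  cat(sprintf("  total wall area %.2f cm^2 (incl. unmeshed sinus %.2f cm^2)\n",
              sum(x$regions$area_cm2),
              sum(x$regions$area_cm2[!x$regions$meshed])))
  tab <- region_area_table(x)
  print(tab, ...)
  invisible(x)
}

#' Regional area table
#'
#' Sums per-cell areas by region (plus configured areas of unmeshed
#' regions) and reports each region's percentage of the total wall area.
#' `percent` carries full precision; `percent_printed` rounds to three
#' significant figures.
#'
#' @param domain An `mc_domain`.
#' @return A data.frame of class `mc_region_table` with columns `region`,
#'   `area_left_cm2`, `area_right_cm2`, `area_cm2`, `percent`,
#'   `percent_printed`.
#' @export
#' @examples
#' region_area_table(build_synthetic_domain(domain_config(resolution_mm = 4)))
region_area_table <- function(domain) {
  reg <- domain$regions
  cells <- domain$cells
  # use the cell accumulation for meshed regions, configured areas otherwise
  meshed_area <- tapply(cells$area_cm2, cells$region, sum)
  split_area <- function(rg, ch) {
    rows <- reg$region == rg & reg$chamber == ch
    if (any(rows)) sum(reg$area_cm2[rows]) else NA_real_
  }
  regions <- unique(reg$region)
  area_left <- vapply(regions, split_area, 0, ch = "left")
  area_right <- vapply(regions, split_area, 0, ch = "right")
  total_by_region <- vapply(regions, function(rg) {
    if (all(reg$meshed[reg$region == rg])) {
      unname(meshed_area[rg])
    } else {
      sum(reg$area_cm2[reg$region == rg])
    }
  }, 0)
  total <- sum(total_by_region)
  out <- data.frame(
    region = regions,
    area_left_cm2 = area_left,
    area_right_cm2 = area_right,
    area_cm2 = unname(total_by_region),
    percent = unname(total_by_region) / total * 100,
    stringsAsFactors = FALSE
  )
  out$percent_printed <- signif(out$percent, 3)
  attr(out, "total_cm2") <- total
  class(out) <- c("mc_region_table", "data.frame")
  out
}

#' Write a domain cell table to CSV
#'
#' @param domain An `mc_domain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_csv <- function(domain, path) {
  cols <- c("x_mm", "y_mm", "area_cm2", "region", "chamber",
            "width_factor", "is_outlet", "is_ostium")
  utils::write.csv(domain$cells[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Load a domain from a cell-table CSV
#'
#' Expects columns `x_mm`, `y_mm`, `area_cm2`, `region`, `width_factor`,
#' `is_outlet`, `is_ostium` (an optional `chamber` column is honoured;
#' without it all cells are treated as one chamber). Cells must sit on a
#' regular grid. Malformed rows are rejected with their row numbers.
#'
#' @param path CSV path.
#' @return An `mc_domain`.
#' @export
load_domain_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_mm", "y_mm", "area_cm2", "region", "width_factor",
            "is_outlet", "is_ostium")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("domain CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!df$region %in% region_names())
  if (length(bad)) {
    stop(sprintf("unknown region name(s) in rows %s: %s",
                 paste(bad, collapse = ", "),
                 paste(unique(df$region[bad]), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$area_cm2) | df$area_cm2 <= 0 |
                 !is.finite(df$width_factor) | df$width_factor <= 0)
  if (length(bad)) {
    stop("non-positive area or width factor in rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("x_mm", "y_mm")])) {
    dup <- which(duplicated(df[, c("x_mm", "y_mm")]))
    stop("duplicate cell coordinates in rows ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$chamber)) df$chamber <- "left"
  xs <- sort(unique(df$x_mm)); ys <- sort(unique(df$y_mm))
  res <- if (length(xs) > 1) min(diff(xs)) else if (length(ys) > 1) min(diff(ys)) else 1
  ix <- as.integer(round((df$x_mm - xs[1]) / res)) + 1L
  iy <- as.integer(round((df$y_mm - ys[1]) / res)) + 1L
  if (anyDuplicated(cbind(ix, iy))) {
    stop("cell coordinates do not sit on a regular grid of spacing ",
         res, call. = FALSE)
  }
  nx <- max(ix); ny <- max(iy)
  cells <- data.frame(
    cell = seq_len(nrow(df)), ix = ix, iy = iy,
    x_mm = df$x_mm, y_mm = df$y_mm, area_cm2 = df$area_cm2,
    region = df$region, chamber = df$chamber,
    width_factor = df$width_factor,
    is_outlet = as.logical(df$is_outlet), is_ostium = as.logical(df$is_ostium),
    stringsAsFactors = FALSE
  )
  index <- matrix(NA_integer_, nrow = ny, ncol = nx)
  index[cbind(iy, ix)] <- cells$cell
  # regional bookkeeping reconstructed from the cells themselves
  agg <- stats::aggregate(area_cm2 ~ region + chamber, data = cells, FUN = sum)
  specs <- region_specs()
  agg$meshed <- TRUE
  agg$absorbing <- specs$absorbing[match(agg$region, specs$region)]
  agg$mucus_producing <- specs$mucus_producing[match(agg$region, specs$region)]
  two <- length(intersect(c("left", "right"), unique(cells$chamber))) == 2
  m <- if (two) {
    max(iy[cells$chamber == "left"])
  } else {
    ny
  }
  dom <- structure(
    list(
      cells = cells,
      regions = agg[, c("region", "chamber", "area_cm2", "meshed",
                        "absorbing", "mucus_producing")],
      nx = nx, ny = ny, res_mm = res,
      two_chambers = two, rows_per_chamber = m,
      naso_x0_col = if (any(cells$region == "nasopharynx")) {
        min(cells$ix[cells$region == "nasopharynx"]) - 1L
      } else {
        nx
      },
      index = index, config = NULL
    ),
    class = "mc_domain"
  )
  validate_domain(dom)
  dom
}

# cell id containing point(s) (x, y) in mm; NA outside the active grid
locate_cells <- function(domain, x_mm, y_mm) {
  ix <- floor(x_mm / domain$res_mm) + 1L
  iy <- floor(y_mm / domain$res_mm) + 1L
  ok <- ix >= 1L & ix <= domain$nx & iy >= 1L & iy <= domain$ny
  out <- rep(NA_integer_, length(x_mm))
  out[ok] <- domain$index[cbind(iy[ok], ix[ok])]
  out
}

# TRUE where the face between two vertically adjacent rows is the sealed
# chamber divide (anterior to the choanae)
chamber_divide <- function(domain, iy_low, ix) {
  if (!domain$two_chambers) return(rep(FALSE, length(ix)))
  iy_low == domain$rows_per_chamber & ix <= domain$naso_x0_col
}
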