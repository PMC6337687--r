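#' Simulated-gel rendering parameters
#'
#' The default ladder mimics a 25-450 bp sizing marker with a render
#' range of 25-500 bp; band migration is linear in log10 fragment size
#' (the standard agarose approximation).
#'
#' @param lane_height vertical run length in pixels.
#' @param lane_width lane width in pixels.
#' @param s_min,s_max smallest/largest renderable fragment (bp).
#' @param ladder sorted ladder fragment sizes (bp), all within
#'   `[s_min, s_max]`.
#' @param well_offset distance from image top to the wells (pixels).
#' @return object of class `gel_params`.
#' @export
gel_params <- function(lane_height = 400, lane_width = 60,
                       s_min = 25, s_max = 500,
                       ladder = c(25, 50, 75, 100, 150, 200, 250, 300,
                                  350, 400, 450),
                       well_offset = 0) {
  if (!(s_min < s_max)) stop("s_min must be < s_max")
  if (any(ladder < s_min | ladder > s_max))
    stop("every ladder size must lie within [s_min, s_max]")
  structure(list(lane_height = lane_height, lane_width = lane_width,
                 s_min = s_min, s_max = s_max, ladder = sort(ladder),
                 well_offset = well_offset),
            class = "gel_params")
}

#' Band migration distance for a fragment size
#'
#' `migration = well_offset + lane_height * (log10(s_max) - log10(size))
#' / (log10(s_max) - log10(s_min))`: strictly decreasing in size, with
#' `s_max` at the well and `s_min` at full migration. Sizes outside the
#' render range are clipped with a warning. Vectorized.
#'
#' @param size fragment sizes in bp.
#' @param params a [gel_params()].
#' @return migration distances in pixels.
#' @export
migration <- function(size, params = gel_params()) {
  out_of_range <- size < params$s_min | size > params$s_max
  if (any(out_of_range)) {
    warning("fragment size outside render range [", params$s_min, ", ",
            params$s_max, "] clipped")
    size <- pmin(pmax(size, params$s_min), params$s_max)
  }
  span <- log10(params$s_max) - log10(params$s_min)
  params$well_offset +
    params$lane_height * (log10(params$s_max) - log10(size)) / span
}

## parse one allele-matrix label into a numeric size vector
.label_sizes <- function(label) {
  if (is.na(label) || label == "NA" || label == "") return(numeric(0))
  if (startsWith(label, "MULTI:"))
    return(as.numeric(strsplit(sub("^MULTI:", "", label), ";",
                               fixed = TRUE)[[1L]]))
  as.numeric(label)
}

#' Render a simulated electrophoresis gel
#'
#' Builds a virtual gel from an allele-size matrix (a
#' [detect_polymorphism()] report or a data.frame whose first column is
#' `locus_id` followed by one column per genotype): a ladder lane
#' first, then one lane per genotype carrying the bands of every
#' rendered locus. MISSING entries give no band; MULTI entries give
#' several bands in one lane. Writes a deterministic SVG plus a band
#' table TSV alongside.
#'
#' @param x a polymorphism report or allele-matrix data.frame.
#' @param params a [gel_params()].
#' @param path SVG output path, or `NULL` for no file.
#' @param locus optional locus_id(s) to restrict the view to.
#' @return object of class `gel_image`: list with `lanes` (ordered
#'   list of `(label, bands)` with `bands` a data.frame of size and
#'   migration) and `band_table`.
#' @export
render_gel <- function(x, params = gel_params(), path = NULL,
                       locus = NULL) {
  mat <- if (inherits(x, "polymorphism_report")) x$matrix else x
  if (!is.data.frame(mat) || names(mat)[1L] != "locus_id")
    stop("expected a polymorphism report or a locus_id + genotype ",
         "allele matrix")
  if (!is.null(locus)) {
    mat <- mat[mat$locus_id %in% locus, , drop = FALSE]
    if (nrow(mat) == 0L) stop("locus not found in matrix: ",
                              paste(locus, collapse = ", "))
  }
  gids <- names(mat)[-1L]
  lanes <- vector("list", length(gids) + 1L)
  lanes[[1L]] <- list(label = "ladder",
                      bands = data.frame(
                        size = params$ladder,
                        migration = migration(params$ladder, params)))
  for (j in seq_along(gids)) {
    sizes <- unlist(lapply(mat[[gids[j]]], .label_sizes),
                    use.names = FALSE)
    bands <- if (length(sizes) > 0L)
      data.frame(size = sizes, migration = migration(sizes, params))
    else data.frame(size = numeric(0), migration = numeric(0))
    lanes[[j + 1L]] <- list(label = gids[j], bands = bands)
  }
  n_bands <- sum(vapply(lanes[-1L], function(l) nrow(l$bands),
                        integer(1L)))
  if (n_bands == 0L) stop("no bands to render (empty matrix)")
  band_table <- do.call(rbind, lapply(seq_along(lanes), function(i) {
    b <- lanes[[i]]$bands
    if (nrow(b) == 0L) return(NULL)
    data.frame(lane = i, label = lanes[[i]]$label, size = b$size,
               migration = b$migration, stringsAsFactors = FALSE)
  }))
  rownames(band_table) <- NULL
  img <- structure(list(lanes = lanes, band_table = band_table,
                        params = params), class = "gel_image")
  if (!is.null(path)) {
    writeLines(.gel_svg(img), path)
    write_tsv(transform(band_table,
                        migration = round(migration, 3L)),
              paste0(tools::file_path_sans_ext(path), "_bands.tsv"))
  }
  img
}

#' @export
print.gel_image <- function(x, ...) {
  cat("Simulated gel:", length(x$lanes), "lanes (incl. ladder),",
      nrow(x$band_table), "bands\n")
  invisible(x)
}

## deterministic SVG text (no timestamps, fixed number formatting)
.gel_svg <- function(img) {
  p <- img$params
  gap <- 12
  n <- length(img$lanes)
  w <- n * (p$lane_width + gap) + gap + 40
  h <- p$well_offset + p$lane_height + 50
  fmt <- function(z) sprintf("%.3f", z)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d" viewBox="0 0 %d %d">'),
                   round(w), round(h), round(w), round(h)),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#101018"/>',
                   round(w), round(h)))
  for (i in seq_len(n)) {
    x0 <- gap + (i - 1) * (p$lane_width + gap)
    lane <- img$lanes[[i]]
    out <- c(out,
             sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="#20202c"/>',
                     fmt(x0), fmt(p$well_offset),
                     fmt(p$lane_width), fmt(p$lane_height)),
             sprintf('<text x="%s" y="%s" fill="#cccccc" font-size="10" text-anchor="middle">%s</text>',
                     fmt(x0 + p$lane_width / 2),
                     fmt(p$well_offset + p$lane_height + 14),
                     lane$label))
    b <- lane$bands
    if (nrow(b) > 0L) {
      ord <- order(b$migration)
      for (k in ord) {
        y <- p$well_offset + (b$migration[k] - p$well_offset)
        out <- c(out,
                 sprintf('<rect x="%s" y="%s" width="%s" height="3" fill="%s"/>',
                         fmt(x0 + 2), fmt(y - 1.5),
                         fmt(p$lane_width - 4),
                         if (i == 1L) "#8888ff" else "#f0f0f0"))
        if (i == 1L)
          out <- c(out,
                   sprintf('<text x="%s" y="%s" fill="#8888ff" font-size="8" text-anchor="end">%s</text>',
                           fmt(x0 - 2), fmt(y + 3),
                           format(b$size[k])))
      }
    }
  }
  c(out, "</svg>")
}
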