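#' Specify an image collection
#'
#' An image collection is the Cartesian product of activity classes,
#' the three landscape variants (heterogeneous, smooth, rugged), the
#' chosen projection methods, and the elevation/azimuth view grids,
#' rendered under one encoding. Seven standard collections are
#' predefined (see [standard_collections()]): collections 1-3 cover all
#' 16 viewpoints and differ in projection (both, MDS only, Neuroscale
#' only); collections 4-7 fix a single elevation (90, 65, 35, 0
#' degrees) and combine both projections.
#'
#' @param projections Subset of `c("mds", "neuroscale")`.
#' @param elevations,azimuths Nonempty view-angle vectors.
#' @param encoding Image encoding variant (see [encode_variant()]).
#' @param name Collection name carried into manifests.
#' @return A `collection_spec` list.
#' @export
collection_spec <- function(projections = c("mds", "neuroscale"),
                            elevations = default_elevations(),
                            azimuths = default_azimuths(),
                            encoding = "color",
                            name = "custom") {
  projections <- match.arg(projections, c("mds", "neuroscale"),
                           several.ok = TRUE)
  stopifnot(length(elevations) >= 1L, length(azimuths) >= 1L)
  structure(list(projections = projections,
                 elevations = as.numeric(elevations),
                 azimuths = as.numeric(azimuths),
                 encoding = encoding, name = name),
            class = "collection_spec")
}

#' The seven standard image collections
#'
#' @param n Collection number 1-7, or `NULL` for the full named list.
#' @param encoding Encoding applied to every collection.
#' @return A `collection_spec`, or a list of all seven.
#' @export
standard_collections <- function(n = NULL, encoding = "color") {
  specs <- list(
    collection_spec(c("mds", "neuroscale"), encoding = encoding, name = "1"),
    collection_spec("mds", encoding = encoding, name = "2"),
    collection_spec("neuroscale", encoding = encoding, name = "3"),
    collection_spec(c("mds", "neuroscale"), elevations = 90,
                    encoding = encoding, name = "4"),
    collection_spec(c("mds", "neuroscale"), elevations = 65,
                    encoding = encoding, name = "5"),
    collection_spec(c("mds", "neuroscale"), elevations = 35,
                    encoding = encoding, name = "6"),
    collection_spec(c("mds", "neuroscale"), elevations = 0,
                    encoding = encoding, name = "7")
  )
  names(specs) <- as.character(1:7)
  if (is.null(n)) specs else specs[[as.character(n)]]
}

#' Expected image count of a collection
#' @param n_classes Number of activity classes.
#' @param spec A [collection_spec()].
#' @return `n_classes * 3 * |projections| * |elevations| * |azimuths|`.
#' @export
collection_size <- function(n_classes, spec) {
  n_classes * 3L * length(spec$projections) *
    length(spec$elevations) * length(spec$azimuths)
}

#' Build the landscape surfaces for a set of activity classes
#'
#' For each class: applies similarity filtering, derives the smooth and
#' rugged reference variants, embeds each variant's fingerprints with
#' the requested projection method(s), fits the Gaussian process
#' potency surface, and evaluates it on a grid. The original class
#' carries the `heterogeneous` variant label. All three variants of a
#' class share a potency axis range (`zlim`, the potency range of the
#' filtered original class) so their vertical relief is rendered on a
#' common scale.
#'
#' @param classes List of [activity_class()] objects (originals).
#' @param projections Subset of `c("mds", "neuroscale")`.
#' @param seed Integer seed (embedding initializations).
#' @param resolution Surface grid nodes per axis.
#' @param filter_threshold Tanimoto similarity filter level.
#' @param ns_candidates Candidate RBF counts for Neuroscale (a single
#'   value skips cross-validation).
#' @param gp_restarts Restarts of the GP hyperparameter search.
#' @param cmap Potency color map.
#' @param progress Print one line per class.
#' @return List of landscape records, each a list with `class`,
#'   `variant`, `projection`, `surface` (a `surface_grid`), `zlim` and
#'   `n_compounds`.
#' @export
build_landscapes <- function(classes, projections = c("mds", "neuroscale"),
                             seed = 1L, resolution = 60L,
                             filter_threshold = 0.4,
                             ns_candidates = NULL,
                             gp_restarts = 2L,
                             cmap = potency_colormap(),
                             progress = FALSE) {
  projections <- match.arg(projections, c("mds", "neuroscale"),
                           several.ok = TRUE)
  out <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[[ci]]
    stopifnot(is_activity_class(cls))
    cls <- similarity_filter(cls, filter_threshold)
    if (length(cls) < 7L) {
      stop("class ", cls$name, " has fewer than 7 compounds after filtering")
    }
    variants <- list(
      heterogeneous = cls,
      smooth = smooth_reference(cls),
      rugged = rugged_reference(cls)
    )
    zlim <- range(cls$potency)
    for (vn in names(variants)) {
      v <- variants[[vn]]
      d <- pairwise_distance_matrix(v)
      for (proj in projections) {
        sseed <- derive_seed(seed, paste0(cls$name, vn, proj))
        emb <- if (proj == "mds") {
          mds_project(d, seed = sseed)
        } else {
          suppressWarnings(
            neuroscale_project(v$fps, d, candidate_counts = ns_candidates,
                               seed = sseed)
          )
        }
        emb <- canonical_orient(emb)
        gp <- gpr_fit(emb$coords, v$potency, restarts = gp_restarts,
                      seed = sseed)
        surf <- gpr_surface(gp, resolution = resolution, cmap = cmap)
        out[[length(out) + 1L]] <- list(
          class = cls$name, variant = vn, projection = proj,
          surface = surf, zlim = zlim, n_compounds = length(v)
        )
      }
    }
    if (progress) {
      message(sprintf("landscapes: %s (%d/%d)", cls$name, ci,
                      length(classes)))
    }
  }
  out
}

#' Render an image collection from prebuilt landscapes
#'
#' Renders one image per (class, variant, projection, elevation,
#' azimuth) combination of the collection specification, applies the
#' crop/resize and encoding pipeline, writes PNGs to `out_dir`, and
#' returns (and writes) the manifest. Existing files whose MD5 checksum
#' matches the stored manifest are not regenerated, making the build
#' resumable.
#'
#' @param landscapes Output of [build_landscapes()].
#' @param spec A [collection_spec()].
#' @param out_dir Output directory (created if necessary).
#' @param width,height Raw render resolution (defaults 1200 x 800).
#' @param feat_width,feat_height Crop/resize target (defaults 360 x
#'   220).
#' @param crop Crop rule passed to [crop_resize()]. Collections default
#'   to a fixed fractional box so every image shares the same framing:
#'   with a content-adaptive crop, a flat (smooth) landscape seen in
#'   profile would be stretched to full frame and its low relief — the
#'   very signal that distinguishes topologies — would be lost.
#' @param canny_low,canny_high Canny thresholds for the canny encoding.
#' @return Manifest data frame with columns `path`, `class`, `variant`,
#'   `projection`, `azimuth`, `elevation`, `encoding`, `md5`; also
#'   written to `manifest.csv` in `out_dir`.
#' @export
render_collection <- function(landscapes, spec, out_dir,
                              width = 1200L, height = 800L,
                              feat_width = 360L, feat_height = 220L,
                              crop = c(0.08, 0.08, 0.92, 0.92),
                              canny_low = 100, canny_high = 200) {
  stopifnot(inherits(spec, "collection_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  old <- if (file.exists(manifest_path)) {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  } else {
    NULL
  }
  keep <- vapply(landscapes, function(l) l$projection %in% spec$projections,
                 logical(1))
  landscapes <- landscapes[keep]
  cls_of <- vapply(landscapes, `[[`, character(1), "class")
  var_of <- vapply(landscapes, `[[`, character(1), "variant")
  incomplete <- names(Filter(
    function(v) !all(c("heterogeneous", "smooth", "rugged") %in% v),
    split(var_of, cls_of)
  ))
  if (length(incomplete)) {
    stop("missing landscape variant(s) for class(es): ",
         paste(incomplete, collapse = ", "))
  }
  rows <- list()
  for (l in landscapes) {
    for (el in spec$elevations) {
      for (az in spec$azimuths) {
        fname <- sprintf("%s_%s_%s_el%03d_az%03d_%s.png",
                         l$class, l$variant, l$projection,
                         as.integer(el), as.integer(az), spec$encoding)
        path <- file.path(out_dir, fname)
        regenerate <- TRUE
        if (!is.null(old) && file.exists(path)) {
          hit <- old[old$path == fname, , drop = FALSE]
          if (nrow(hit) == 1L &&
              identical(unname(tools::md5sum(path)), hit$md5)) {
            regenerate <- FALSE
          }
        }
        if (regenerate) {
          img <- render_landscape(
            l$surface, view_spec(az, el), width = width, height = height,
            zlim = l$zlim,
            meta = list(class = l$class, variant = l$variant,
                        projection = l$projection)
          )
          img <- crop_resize(img, width = feat_width, height = feat_height,
                             crop = crop)
          img <- encode_variant(img, spec$encoding,
                                canny_low = canny_low,
                                canny_high = canny_high)
          write_image(img, path)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          path = fname, class = l$class, variant = l$variant,
          projection = l$projection, azimuth = az, elevation = el,
          encoding = spec$encoding,
          md5 = unname(tools::md5sum(path)),
          regenerated = regenerate,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest[, setdiff(names(manifest), "regenerated")],
                   manifest_path, row.names = FALSE, quote = FALSE)
  manifest
}

#' Build an image collection from activity classes
#'
#' Convenience composition of [build_landscapes()] and
#' [render_collection()].
#'
#' @inheritParams build_landscapes
#' @inheritParams render_collection
#' @param ... Passed on to [render_collection()].
#' @return The manifest data frame.
#' @export
build_collection <- function(classes, spec, out_dir, seed = 1L,
                             resolution = 60L, ns_candidates = NULL,
                             ...) {
  landscapes <- build_landscapes(classes, projections = spec$projections,
                                 seed = seed, resolution = resolution,
                                 ns_candidates = ns_candidates)
  render_collection(landscapes, spec, out_dir, ...)
}

# deterministic 31-bit stream seed from a master seed and a stage label
derive_seed <- function(master, label) {
  h <- string_hash(paste0(label, ":", master))
  as.integer((h + as.numeric(master) * 2654435761) %% 2147483629 + 1)
}
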