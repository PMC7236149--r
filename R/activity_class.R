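#' Construct an activity class
#'
#' An activity class bundles the compounds of one target-based data set:
#' compound identifiers, binary fingerprints (one row per compound) and
#' potencies on the pKi scale (negative decadic logarithm of the
#' inhibition constant). It is the unit from which one activity
#' landscape is built. The `variant` label records whether the class is
#' an original (heterogeneous) set or a smooth/rugged reference
#' selection derived from one.
#'
#' @param name Class name (e.g. a target identifier).
#' @param ids Character vector of unique compound identifiers.
#' @param fps Integer 0/1 matrix of fingerprints, `length(ids)` rows.
#' @param potency Numeric vector of finite pKi values.
#' @param variant One of `"heterogeneous"`, `"smooth"`, `"rugged"`.
#' @return An object of class `activity_class`: a list with elements
#'   `name`, `ids`, `fps`, `potency`, `variant`.
#' @examples
#' fps <- matrix(rbinom(5 * 64, 1, 0.3), nrow = 5)
#' cls <- activity_class("toy", paste0("c", 1:5), fps, potency = 5:9)
#' cls
#' @export
activity_class <- function(name, ids, fps, potency,
                           variant = c("heterogeneous", "smooth", "rugged")) {
  variant <- match.arg(variant)
  ids <- as.character(ids)
  fps <- as_fp_matrix(fps)
  potency <- as.numeric(potency)
  if (anyDuplicated(ids)) stop("compound ids must be unique within a class")
  if (nrow(fps) != length(ids) || length(potency) != length(ids)) {
    stop("ids, fps rows and potency must have equal lengths")
  }
  if (any(!is.finite(potency))) {
    stop("non-finite potency for compound(s): ",
         paste(ids[!is.finite(potency)], collapse = ", "))
  }
  rownames(fps) <- ids
  structure(
    list(name = as.character(name)[1], ids = ids, fps = fps,
         potency = potency, variant = variant),
    class = "activity_class"
  )
}

#' @export
print.activity_class <- function(x, ...) {
  cat(sprintf("<activity_class> %s (%s): %d compounds, %d-bit fingerprints\n",
              x$name, x$variant, length(x$ids), ncol(x$fps)))
  if (length(x$potency)) {
    cat(sprintf("  potency [pKi]: %.2f .. %.2f\n",
                min(x$potency), max(x$potency)))
  }
  invisible(x)
}

#' @export
length.activity_class <- function(x) length(x$ids)

#' Test whether an object is an activity class
#' @param x Any object.
#' @return Logical scalar.
#' @export
is_activity_class <- function(x) inherits(x, "activity_class")

# subset by index, keeping metadata
ac_subset <- function(cls, idx, variant = cls$variant) {
  activity_class(cls$name, cls$ids[idx], cls$fps[idx, , drop = FALSE],
                 cls$potency[idx], variant = variant)
}

#' Potency distribution summary of an activity class
#'
#' Quartiles and septile boundaries of the potency distribution;
#' quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param cls An [activity_class()].
#' @return List with `min`, `max`, `q1`, `q3`, `iqr` and
#'   `septile_boundaries` (the 6 interior septile quantiles), all in pKi
#'   units.
#' @export
potency_summary <- function(cls) {
  stopifnot(is_activity_class(cls))
  p <- cls$potency
  q <- stats::quantile(p, c(0.25, 0.75), names = FALSE, type = 7)
  list(min = min(p), max = max(p), q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
       septile_boundaries = stats::quantile(p, (1:6) / 7, names = FALSE, type = 7))
}

#' Remove structural singletons by Tanimoto similarity filtering
#'
#' Retains exactly the compounds that have a Tanimoto similarity of at
#' least `threshold` (default 0.4) to at least one other compound of the
#' same class; singletons without such a neighbor contribute no
#' structure-activity information and are dropped. Because neighbor
#' relations are mutual, removing singletons cannot create new ones, so
#' a single pass suffices and the operation is idempotent.
#'
#' @param cls An [activity_class()].
#' @param threshold Minimum similarity to at least one other compound.
#' @return The filtered [activity_class()] (possibly empty, with a
#'   warning).
#' @export
similarity_filter <- function(cls, threshold = 0.4) {
  stopifnot(is_activity_class(cls))
  n <- length(cls)
  if (n <= 1L) {
    if (n == 1L) warning("similarity filtering removed all compounds of ", cls$name)
    return(ac_subset(cls, integer(0)))
  }
  tc <- tanimoto_matrix(cls$fps)
  diag(tc) <- -Inf
  keep <- apply(tc, 1L, max) >= threshold
  if (!any(keep)) {
    warning("similarity filtering removed all compounds of ", cls$name)
  }
  ac_subset(cls, which(keep))
}

#' Smooth reference landscape selection (interquartile potencies)
#'
#' Builds the smooth reference variant of a class by keeping the
#' compounds whose potency falls into the interquartile range
#' `[q1, q3]` (closed interval, boundary ties included). Restricting the
#' potency spread suppresses activity cliffs and exaggerates
#' structure-activity continuity; for well-spread potencies about half
#' of the compounds are retained.
#'
#' @param cls An [activity_class()] with at least 4 compounds.
#' @return An [activity_class()] with `variant = "smooth"`.
#' @seealso [rugged_reference()]
#' @export
smooth_reference <- function(cls) {
  stopifnot(is_activity_class(cls))
  if (length(cls) < 4L) stop("smooth_reference requires at least 4 compounds")
  s <- potency_summary(cls)
  idx <- which(cls$potency >= s$q1 & cls$potency <= s$q3)
  if (length(idx) < 2L) {
    stop("smooth reference selection left fewer than 2 compounds")
  }
  ac_subset(cls, idx, variant = "smooth")
}

#' Rugged reference landscape selection (alternating septiles)
#'
#' Builds the rugged reference variant by sorting compounds by potency
#' (ties broken by id), partitioning them into 7 consecutive bins of
#' near-equal count (any remainder goes to the earliest bins) and
#' keeping bins 1, 3, 5 and 7. The alternating gaps plant large potency
#' differences between structural neighbors, exaggerating
#' structure-activity discontinuity, while the global potency range of
#' the class is retained. For `n` divisible by 7 exactly `4n/7`
#' compounds are selected.
#'
#' @param cls An [activity_class()] with at least 7 compounds.
#' @return An [activity_class()] with `variant = "rugged"`.
#' @seealso [smooth_reference()]
#' @export
rugged_reference <- function(cls) {
  stopifnot(is_activity_class(cls))
  n <- length(cls)
  if (n < 7L) stop("rugged_reference requires at least 7 compounds")
  ord <- order(cls$potency, cls$ids)
  base <- n %/% 7L
  rem <- n %% 7L
  sizes <- rep(base, 7L) + c(rep(1L, rem), rep(0L, 7L - rem))
  bin <- rep(1:7, times = sizes)
  idx <- sort(ord[bin %in% c(1L, 3L, 5L, 7L)])
  ac_subset(cls, idx, variant = "rugged")
}

# ---- compound table I/O ----------------------------------------------------

#' Read an activity class from a compound CSV table
#'
#' Expects a header with columns `id`, `potency` and `fingerprint`
#' (and optionally `smiles`). Fingerprints are given either as '0'/'1'
#' bit strings or as hexadecimal (most-significant-bit-first, see
#' [fp_to_hex()]); all fingerprints in one file must decode to the same
#' length. Alternatively, when a `smiles` column is present, a
#' `fingerprinter` function mapping a SMILES string to a 0/1 vector may
#' be supplied to compute fingerprints on the fly.
#'
#' @param path Path to a CSV file.
#' @param name Class name; defaults to the file name without extension.
#' @param variant Variant label for the class.
#' @param fingerprinter Optional `function(smiles) -> 0/1 vector` used
#'   when the table has no `fingerprint` column.
#' @return An [activity_class()]. Malformed rows raise an error naming
#'   the offending row numbers.
#' @seealso [write_compound_table()]
#' @export
read_compound_table <- function(path, name = NULL,
                                variant = "heterogeneous",
                                fingerprinter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  need <- c("id", "potency")
  missing_cols <- setdiff(need, names(df))
  if (!("fingerprint" %in% names(df)) && is.null(fingerprinter)) {
    missing_cols <- c(missing_cols, "fingerprint")
  }
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty compound table: ", path)

  potency <- suppressWarnings(as.numeric(df$potency))
  bad <- which(!is.finite(potency))
  if (length(bad)) {
    stop("non-finite potency in ", path, " at row(s): ",
         paste(bad, collapse = ", "))
  }

  fps_list <- if ("fingerprint" %in% names(df)) {
    lapply(seq_len(nrow(df)), function(i) {
      s <- trimws(df$fingerprint[i])
      tryCatch(
        if (grepl("^[01]+$", s)) fp_from_bitstring(s) else fp_from_hex(s),
        error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                 call. = FALSE)
      )
    })
  } else {
    lapply(seq_len(nrow(df)), function(i) {
      tryCatch(as_fp_bits(fingerprinter(df$smiles[i])),
               error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                        call. = FALSE))
    })
  }
  lens <- lengths(fps_list)
  if (length(unique(lens)) != 1L) {
    stop("inconsistent fingerprint lengths in ", path, " at row(s): ",
         paste(which(lens != lens[1]), collapse = ", "))
  }
  activity_class(name, df$id, do.call(rbind, fps_list), potency,
                 variant = variant)
}

#' Write an activity class to a compound CSV table
#'
#' @param cls An [activity_class()].
#' @param path Output CSV path.
#' @param format Fingerprint serialization, `"bitstring"` or `"hex"`.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(cls, path, format = c("bitstring", "hex")) {
  stopifnot(is_activity_class(cls))
  format <- match.arg(format)
  ser <- if (format == "hex") fp_to_hex else fp_to_bitstring
  fp <- vapply(seq_len(length(cls)),
               function(i) ser(cls$fps[i, ]), character(1))
  utils::write.csv(
    data.frame(id = cls$ids, potency = cls$potency, fingerprint = fp,
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' ECFP-style hashed circular fingerprint from a SMILES string
#'
#' A pluggable fingerprinter for [read_compound_table()]: hashed
#' circular substructure environments up to the given radius, folded
#' into a fixed-length bit vector by modulo. Atom environments are
#' derived from a minimal SMILES graph parse (atoms and bonds; no
#' aromaticity perception beyond lower-case aromatic atom symbols).
#' This is a generic circular fingerprint; different toolkits produce
#' different (non-interchangeable) bit assignments for the same
#' molecule, so fingerprints should be computed consistently with one
#' tool per data set.
#'
#' @param smiles SMILES string.
#' @param nbits Folded length (default 1024).
#' @param radius Neighborhood radius in bonds (default 2, i.e. ECFP4).
#' @return Integer 0/1 vector of length `nbits`.
#' @export
circular_fingerprint <- function(smiles, nbits = 1024L, radius = 2L) {
  g <- parse_smiles_graph(smiles)
  if (length(g$atoms) == 0L) stop("no atoms parsed from SMILES: ", smiles)
  # initial invariants: element symbol + degree
  ids <- vapply(seq_along(g$atoms), function(i) {
    string_hash(paste0(g$atoms[i], ":", length(g$adj[[i]])))
  }, numeric(1))
  feats <- ids
  for (r in seq_len(radius)) {
    ids <- vapply(seq_along(g$atoms), function(i) {
      nb <- sort(ids[g$adj[[i]]])
      string_hash(paste(c(r, ids[i], nb), collapse = "|"))
    }, numeric(1))
    feats <- c(feats, ids)
  }
  bits <- integer(nbits)
  bits[(as.integer(feats %% nbits)) + 1L] <- 1L
  bits
}

# minimal SMILES parser: organic-subset atoms, branches, ring closures
parse_smiles_graph <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  atoms <- character(0)
  adj <- list()
  stack <- integer(0)
  prev <- 0L
  rings <- list()
  i <- 1L
  add_bond <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev)
    } else if (ch == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", ".")) {
      # bond orders are ignored for connectivity hashing
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      sym <- paste(chars[(i + 1):(j - 1)], collapse = "")
      atoms <- c(atoms, sym)
      adj[[length(atoms)]] <- integer(0)
      if (prev > 0L) add_bond(prev, length(atoms))
      prev <- length(atoms)
      i <- j
    } else if (grepl("[0-9%]", ch)) {
      key <- ch
      if (ch == "%") {
        key <- paste(chars[(i + 1):(i + 2)], collapse = "")
        i <- i + 2L
      }
      if (!is.null(rings[[key]])) {
        add_bond(rings[[key]], prev)
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- prev
      }
    } else if (grepl("[A-Za-z]", ch)) {
      sym <- ch
      if (ch %in% c("C", "B") && i < length(chars) &&
          chars[i + 1] %in% c("l", "r")) {
        sym <- paste0(ch, chars[i + 1])
        i <- i + 1L
      }
      atoms <- c(atoms, sym)
      adj[[length(atoms)]] <- integer(0)
      if (prev > 0L) add_bond(prev, length(atoms))
      prev <- length(atoms)
    }
    i <- i + 1L
  }
  list(atoms = atoms, adj = adj)
}

# deterministic 31-bit string hash (polynomial rolling hash)
string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  h
}
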