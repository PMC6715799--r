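#' Construct a coda
#'
#' A coda is a stereotyped sequence of clicks represented here by its vector
#' of inter-click intervals (ICIs, the absolute times in seconds between
#' successive clicks), plus optional annotations: categorical coda type,
#' vocal clan membership, and individual whale identity.
#'
#' @param icis Numeric vector of positive ICIs (length = n_clicks - 1, >= 1).
#' @param type Optional coda type label (non-empty string).
#' @param clan Optional vocal clan label.
#' @param whale Optional individual whale identifier.
#' @param source Dataset provenance tag.
#' @return An object of class `coda`.
#' @export
coda <- function(icis, type = NA_character_, clan = NA_character_,
                 whale = NA_character_, source = NA_character_) {
  icis <- as.numeric(icis)
  if (length(icis) < 1L || any(!is.finite(icis)) || any(icis <= 0)) {
    stop("`icis` must be a non-empty vector of positive, finite seconds")
  }
  for (lab in list(type, clan, whale)) {
    if (!is.na(lab) && !nzchar(lab)) stop("labels, when present, must be non-empty")
  }
  structure(
    list(icis = icis, type = as.character(type), clan = as.character(clan),
         whale = as.character(whale), source = as.character(source)),
    class = "coda"
  )
}

#' Construct a coda dataset
#'
#' An ordered collection of [coda()] objects with per-label vocabularies
#' (the sorted distinct labels actually present).
#'
#' @param codas List of [coda()] objects.
#' @param provenance Free-text description of the dataset's origin.
#' @return An object of class `coda_dataset`.
#' @export
coda_dataset <- function(codas, provenance = NA_character_) {
  stopifnot(is.list(codas))
  if (length(codas) && !all(vapply(codas, inherits, logical(1), "coda"))) {
    stop("all elements must be `coda` objects")
  }
  structure(
    list(codas = codas, provenance = provenance),
    class = "coda_dataset"
  )
}

#' @export
length.coda_dataset <- function(x) length(x$codas)

#' @export
print.coda_dataset <- function(x, ...) {
  cat(sprintf("<coda_dataset: %d codas%s>\n", length(x$codas),
              if (is.na(x$provenance)) "" else paste0(" (", x$provenance, ")")))
  for (kind in c("type", "clan", "whale")) {
    v <- label_vocabulary(x, kind)
    if (length(v)) cat(" ", kind, ":", length(v), "classes\n")
  }
  invisible(x)
}

coda_labels <- function(ds, label_kind) {
  label_kind <- match.arg(label_kind, c("type", "clan", "whale"))
  vapply(ds$codas, `[[`, character(1), label_kind)
}

#' Label vocabulary of a coda dataset
#'
#' @param ds A [coda_dataset()].
#' @param label_kind One of `"type"`, `"clan"`, `"whale"`.
#' @return Sorted character vector of the distinct non-missing labels.
#' @export
label_vocabulary <- function(ds, label_kind) {
  labs <- coda_labels(ds, label_kind)
  sort(unique(labs[!is.na(labs)]))
}

#' Read an annotated coda table from delimited text
#'
#' Ingests one coda per row. ICI values may be spread over a set of columns
#' (blank or zero trailing cells are treated as padding and dropped) or
#' packed into one delimited cell. CSV and TSV are auto-detected from the
#' file extension.
#'
#' @param path Path to the delimited text file.
#' @param column_map Named list describing the layout: either `ici` (a
#'   character vector of ICI column names) or `ici_prefix` (all columns whose
#'   name starts with the prefix, in order) or `ici_packed` (a single column
#'   of `ici_sep`-separated values, default separator `";"`); plus optional
#'   `type`, `clan`, `whale`, `source` entries naming the label columns.
#' @param provenance Provenance tag stored on the dataset and each coda.
#' @return A [coda_dataset()].
#' @export
read_coda_table <- function(path,
                            column_map = list(ici_prefix = "ici",
                                              type = "type", clan = "clan",
                                              whale = "whale"),
                            provenance = basename(path)) {
  if (!file.exists(path)) stop("cannot read coda table: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  known <- c("ici", "ici_prefix", "ici_packed", "ici_sep",
             "type", "clan", "whale", "source")
  bad <- setdiff(names(column_map), known)
  if (length(bad)) stop("unknown column_map entries: ", paste(bad, collapse = ", "))
  for (nm in intersect(c("ici", "type", "clan", "whale", "source"),
                       names(column_map))) {
    missing_cols <- setdiff(column_map[[nm]], names(tab))
    if (length(missing_cols)) {
      stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
    }
  }
  parse_cell <- function(chr, row) {
    v <- suppressWarnings(as.numeric(chr))
    bad <- !is.na(chr) & is.na(v)
    if (any(bad)) {
      stop(sprintf("malformed numeric cell '%s' in row %d",
                   chr[which(bad)[1]], row))
    }
    v
  }
  get_icis <- function(i) {
    if (!is.null(column_map[["ici_packed"]])) {
      cell <- tab[[column_map[["ici_packed"]]]][i]
      if (is.na(cell)) return(numeric(0))
      parse_cell(strsplit(cell, column_map[["ici_sep"]] %||% ";")[[1]], i)
    } else {
      cols <- if (!is.null(column_map[["ici"]])) column_map[["ici"]] else
        names(tab)[startsWith(names(tab), column_map[["ici_prefix"]])]
      if (!length(cols)) stop("no ICI columns found in table")
      parse_cell(unlist(tab[i, cols], use.names = FALSE), i)
    }
  }
  get_label <- function(i, kind) {
    col <- column_map[[kind]]
    if (is.null(col)) NA_character_ else tab[[col]][i]
  }
  codas <- vector("list", nrow(tab))
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- get_icis(i)
    v <- v[!is.na(v)]
    # trailing zero cells are padding
    while (length(v) && v[length(v)] == 0) v <- v[-length(v)]
    v <- v[v > 0]
    if (!length(v)) next
    keep[i] <- TRUE
    codas[[i]] <- coda(v,
                       type = get_label(i, "type"),
                       clan = get_label(i, "clan"),
                       whale = get_label(i, "whale"),
                       source = if (!is.null(column_map[["source"]]))
                         get_label(i, "source") else provenance)
  }
  coda_dataset(codas[keep], provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a coda dataset as delimited text
#'
#' Canonical schema: one row per coda with columns `ici_1..ici_k` (blank
#' padded), `type`, `clan`, `whale`, `source`.
#'
#' @param ds A [coda_dataset()].
#' @param path Output path (`.tsv`/`.txt` for tab-separated, else CSV).
#' @return `path`, invisibly.
#' @export
write_coda_table <- function(ds, path) {
  stopifnot(inherits(ds, "coda_dataset"))
  k <- max(vapply(ds$codas, function(cd) length(cd$icis), integer(1)), 1L)
  mat <- matrix(NA_real_, length(ds$codas), k)
  for (i in seq_along(ds$codas)) {
    v <- ds$codas[[i]]$icis
    mat[i, seq_along(v)] <- v
  }
  out <- as.data.frame(mat)
  names(out) <- paste0("ici_", seq_len(k))
  out$type <- coda_labels(ds, "type")
  out$clan <- coda_labels(ds, "clan")
  out$whale <- coda_labels(ds, "whale")
  out$source <- vapply(ds$codas, `[[`, character(1), "source")
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

#' Filter a coda dataset
#'
#' Order-preserving restriction of the dataset, mirroring the cohort rules
#' used in coda studies: a maximum click count (n_clicks = n_icis + 1), a
#' maximum ICI-vector length, presence of a given label kind, and removal of
#' configurable label values (e.g. noise categories).
#'
#' @param ds A [coda_dataset()].
#' @param max_clicks Optional maximum number of clicks per coda.
#' @param max_icis Optional maximum number of ICIs per coda.
#' @param require_label Optional label kind (`"type"`, `"clan"`, `"whale"`)
#'   that must be present (non-missing).
#' @param drop_labels Optional character vector of label values to remove.
#' @param drop_label_kind Label kind that `drop_labels` refers to.
#' @return The filtered [coda_dataset()].
#' @export
filter_codas <- function(ds, max_clicks = NULL, max_icis = NULL,
                         require_label = NULL, drop_labels = NULL,
                         drop_label_kind = "type") {
  stopifnot(inherits(ds, "coda_dataset"))
  keep <- rep(TRUE, length(ds$codas))
  len <- vapply(ds$codas, function(cd) length(cd$icis), integer(1))
  if (!is.null(max_clicks)) keep <- keep & (len + 1L <= max_clicks)
  if (!is.null(max_icis)) keep <- keep & (len <= max_icis)
  if (!is.null(require_label)) {
    keep <- keep & !is.na(coda_labels(ds, require_label))
  }
  if (!is.null(drop_labels)) {
    labs <- coda_labels(ds, drop_label_kind)
    keep <- keep & !(labs %in% drop_labels)
  }
  coda_dataset(ds$codas[keep], provenance = ds$provenance)
}

#' Downsample classes to equal size
#'
#' Draws, without replacement and reproducibly for a fixed seed, the minimum
#' class count from every class under the given label kind, removing class
#' imbalance before two-class analyses.
#'
#' @param ds A [coda_dataset()] with at least two classes under `label_kind`.
#' @param label_kind `"type"`, `"clan"`, or `"whale"`.
#' @param seed Integer seed.
#' @return A balanced [coda_dataset()] of size n_classes x min class count,
#'   in the original relative order.
#' @export
balance_classes <- function(ds, label_kind, seed = 1L) {
  labs <- coda_labels(ds, label_kind)
  if (any(is.na(labs))) stop("all codas must carry the `", label_kind, "` label")
  counts <- table(labs)
  if (length(counts) < 2L) stop("need >= 2 classes to balance, found ",
                                length(counts))
  m <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(names(counts), function(cl) {
    sample(which(labs == cl), m)
  }))
  keep <- sort(keep)
  coda_dataset(ds$codas[keep], provenance = ds$provenance)
}

#' Split a coda dataset into disjoint training and testing sets
#'
#' The test size is `ceiling(n * test_fraction)`. With `stratify_by`, test
#' counts per class are allocated by largest remainder so every class stays
#' within one coda of exact proportionality.
#'
#' @param ds A [coda_dataset()].
#' @param test_fraction Fraction in (0, 1) held out for testing.
#' @param seed Integer seed.
#' @param stratify_by Optional label kind to stratify on.
#' @return A list with `train` and `test` datasets; their union is a
#'   permutation-free partition of the input.
#' @export
split_train_test <- function(ds, test_fraction, seed = 1L,
                             stratify_by = NULL) {
  stopifnot(inherits(ds, "coda_dataset"),
            test_fraction > 0, test_fraction < 1)
  n <- length(ds$codas)
  n_test <- as.integer(ceiling(n * test_fraction))
  if (n_test == 0L || n_test == n) {
    stop("split would leave an empty train or test set (n = ", n, ")")
  }
  set.seed(seed)
  if (is.null(stratify_by)) {
    test_idx <- sample.int(n, n_test)
  } else {
    labs <- coda_labels(ds, stratify_by)
    if (any(is.na(labs))) {
      stop("all codas must carry the `", stratify_by, "` label to stratify")
    }
    counts <- table(labs)
    ideal <- as.numeric(counts) * n_test / n
    base <- floor(ideal)
    rem <- n_test - sum(base)
    if (rem > 0) {
      extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    test_idx <- unlist(lapply(seq_along(counts), function(j) {
      pool <- which(labs == names(counts)[j])
      if (base[j] > 0) sample(pool, base[j]) else integer(0)
    }))
  }
  test_idx <- sort(test_idx)
  list(
    train = coda_dataset(ds$codas[-test_idx], provenance = ds$provenance),
    test = coda_dataset(ds$codas[test_idx], provenance = ds$provenance)
  )
}

#' Encode labels as contiguous integer classes
#'
#' @param ds A [coda_dataset()]; every coda must carry the label kind.
#' @param label_kind `"type"`, `"clan"`, or `"whale"`.
#' @return A list with `mapping` (named integer vector, sorted vocabulary ->
#'   0-based class index) and `labels` (integer class per coda).
#' @export
encode_labels <- function(ds, label_kind) {
  labs <- coda_labels(ds, label_kind)
  if (any(is.na(labs))) {
    stop("codas missing `", label_kind, "` label at positions: ",
         paste(utils::head(which(is.na(labs)), 10), collapse = ", "))
  }
  vocab <- sort(unique(labs))
  mapping <- stats::setNames(seq_along(vocab) - 1L, vocab)
  list(mapping = mapping, labels = unname(mapping[labs]))
}

#' Decode integer classes back to labels
#'
#' @param encoded Integer class vector (0-based).
#' @param mapping The mapping from [encode_labels()].
#' @return Character labels.
#' @export
decode_labels <- function(encoded, mapping) {
  names(mapping)[match(encoded, mapping)]
}
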