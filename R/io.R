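#' Read a MIML dataset from the plain-text bag-table format
#'
#' The bag table is a UTF-8 TSV with header `bag_id<TAB>f1<TAB>...<TAB>fd`;
#' one row per instance, instance order within a bag is file order, and one
#' bag is formed per distinct `bag_id` (in order of first appearance). The
#' labels table is a TSV with header `bag_id<TAB>labels`, where `labels` is
#' a comma-separated list of class identifiers (empty allowed). An optional
#' comment line `#classes<TAB>id1,id2,...` before the labels header fixes
#' the full class vocabulary (including classes with no positive bag);
#' without it the vocabulary is the union of observed labels in order of
#' first appearance.
#'
#' This is also the interchange format a converter from the LAMDA
#' MIMLprotein archive would target: one row per protein-domain conjoint
#' triad vector (d = 216), one label row per protein listing its GO
#' molecular-function terms.
#'
#' @param path_bags path to the bag table.
#' @param path_labels path to the labels table, or `NULL` for an unlabeled
#'   dataset.
#' @param domain domain tag for the resulting dataset.
#' @return A [miml_dataset()].
#' @seealso [write_miml_table()]
#' @export
read_miml_table <- function(path_bags, path_labels = NULL,
                            domain = "unsplit") {
  if (!file.exists(path_bags)) stop("bag table not found: ", path_bags)
  lines <- readLines(path_bags, encoding = "UTF-8")
  if (length(lines) < 2L) stop("bag table has no instance rows: ", path_bags)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "bag_id" || length(header) < 2L) {
    stop("bag table header must be 'bag_id<TAB>f1...fd'")
  }
  d <- length(header) - 1L
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- character(length(rows))
  feats <- matrix(NA_real_, length(rows), d)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != d + 1L) {
      stop("bag table row ", i + 1L, " has ", length(r) - 1L,
           " feature(s) but header declares ", d)
    }
    ids[i] <- r[1L]
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v)) {
      stop("non-numeric feature value in bag table row ", i + 1L,
           " (bag '", r[1L], "')")
    }
    feats[i, ] <- v
  }
  uid <- unique(ids)
  bags <- lapply(uid, function(id) {
    new_bag(feats[ids == id, , drop = FALSE], id)
  })

  class_ids <- character(0)
  label_sets <- setNames(vector("list", length(uid)), uid)
  if (!is.null(path_labels)) {
    if (!file.exists(path_labels)) stop("labels table not found: ", path_labels)
    llines <- readLines(path_labels, encoding = "UTF-8")
    if (length(llines) >= 1L && startsWith(llines[1L], "#classes\t")) {
      voc <- sub("^#classes\t", "", llines[1L])
      class_ids <- if (nzchar(voc)) strsplit(voc, ",", fixed = TRUE)[[1L]] else character(0)
      llines <- llines[-1L]
    }
    if (length(llines) < 1L || !identical(llines[1L], "bag_id\tlabels")) {
      stop("labels table header must be 'bag_id<TAB>labels'")
    }
    for (ln in llines[-1L]) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      id <- parts[1L]
      if (!id %in% uid) {
        stop("bag_id '", id, "' appears in the labels table but not in the bag table")
      }
      labs <- if (length(parts) >= 2L && nzchar(parts[2L])) {
        strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
      } else character(0)
      label_sets[[id]] <- labs
      class_ids <- union(class_ids, labs)
    }
  }
  Y <- matrix(0, length(uid), length(class_ids))
  for (i in seq_along(uid)) {
    labs <- label_sets[[uid[i]]]
    if (length(labs)) Y[i, match(labs, class_ids)] <- 1
  }
  miml_dataset(bags, Y, class_ids = class_ids, domain = domain)
}

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a MIML dataset in the plain-text bag-table format
#'
#' Instance values are written with 15 significant digits, so a round trip
#' through [read_miml_table()] reproduces them to at least 12 significant
#' digits; bag structure and the label matrix (including empty classes, via
#' the `#classes` vocabulary line) round-trip exactly.
#'
#' @param dataset a [miml_dataset()].
#' @param path_bags,path_labels output paths; `path_labels = NULL` skips the
#'   labels table.
#' @return Invisibly, `NULL`.
#' @export
write_miml_table <- function(dataset, path_bags, path_labels = NULL) {
  stopifnot(inherits(dataset, "mimtl_dataset"))
  d <- dataset$d
  con <- file(path_bags, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("bag_id", paste0("f", seq_len(d))), collapse = "\t"),
             con, sep = "\n")
  for (b in dataset$bags) {
    for (i in seq_len(nrow(b$instances))) {
      writeLines(paste(c(b$bag_id, fmt_num(b$instances[i, ])), collapse = "\t"),
                 con, sep = "\n")
    }
  }
  if (!is.null(path_labels)) {
    lcon <- file(path_labels, "wb")
    on.exit(close(lcon), add = TRUE)
    writeLines(paste0("#classes\t", paste(dataset$class_ids, collapse = ",")),
               lcon, sep = "\n")
    writeLines("bag_id\tlabels", lcon, sep = "\n")
    for (i in seq_len(n_bags(dataset))) {
      labs <- dataset$class_ids[dataset$labels[i, ] == 1]
      writeLines(paste(dataset$bags[[i]]$bag_id,
                       paste(labs, collapse = ","), sep = "\t"),
                 lcon, sep = "\n")
    }
  }
  invisible(NULL)
}
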