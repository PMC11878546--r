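#' Directory-backed hierarchical result store
#'
#' A dataset's raw counts and every intermediate result live in one store on
#' disk so that later pipeline stages (and re-runs with new thresholds) read
#' earlier stages back instead of recomputing them. The store is a directory
#' with one subdirectory per group (`counts`, `wildtype`, `bm_fit`, `bb_fit`,
#' `pvals`, `calls`); each dataset is an RDS file, with optional attributes
#' (creation parameters, tool version) in a JSON sidecar. Reading a persisted
#' object back reproduces it bit-exactly.
#'
#' @param path store directory; created if absent.
#' @return a `store_handle`.
#' @export
store_open <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  structure(list(path = normalizePath(path)), class = "store_handle")
}

STORE_GROUPS <- c("counts", "wildtype", "bm_fit", "bb_fit", "pvals", "calls")

store_file <- function(store, group, name) {
  stopifnot(inherits(store, "store_handle"))
  if (!group %in% STORE_GROUPS) stop("unknown store group: ", group)
  file.path(store$path, group, paste0(name, ".rds"))
}

#' Write a dataset into a store group
#' @param store a `store_handle`.
#' @param group one of `counts`, `wildtype`, `bm_fit`, `bb_fit`, `pvals`, `calls`.
#' @param name dataset name.
#' @param value any R object.
#' @param attrs optional named list of attributes (parameters, version) kept
#'   alongside the dataset as JSON.
#' @export
store_write <- function(store, group, name, value, attrs = NULL) {
  f <- store_file(store, group, name)
  dir.create(dirname(f), showWarnings = FALSE, recursive = TRUE)
  saveRDS(value, f)
  if (!is.null(attrs)) {
    jsonlite::write_json(attrs, paste0(f, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(store)
}

#' Read a dataset back from a store
#' @inheritParams store_write
#' @param missing_hint optional message appended when the dataset is absent,
#'   telling the user which pipeline step produces it.
#' @export
store_read <- function(store, group, name, missing_hint = NULL) {
  f <- store_file(store, group, name)
  if (!file.exists(f)) {
    stop("store has no dataset '", name, "' in group '", group, "'",
         if (!is.null(missing_hint)) paste0("; ", missing_hint) else "")
  }
  readRDS(f)
}

#' Read a dataset's attributes (NULL when none were written)
#' @inheritParams store_read
#' @export
store_attrs <- function(store, group, name) {
  f <- paste0(store_file(store, group, name), ".json")
  if (!file.exists(f)) return(NULL)
  jsonlite::read_json(f, simplifyVector = TRUE)
}

#' Does a dataset exist in the store?
#' @inheritParams store_read
#' @export
store_exists <- function(store, group, name) file.exists(store_file(store, group, name))

#' List datasets, per group or store-wide
#' @param store a `store_handle`.
#' @param group optional group name.
#' @export
store_list <- function(store, group = NULL) {
  groups <- if (is.null(group)) STORE_GROUPS else group
  out <- lapply(groups, function(g) {
    fs <- list.files(file.path(store$path, g), pattern = "\\.rds$")
    sub("\\.rds$", "", fs)
  })
  names(out) <- groups
  out
}

#' @export
print.store_handle <- function(x, ...) {
  cat("result store at", x$path, "\n")
  li <- store_list(x)
  for (g in names(li)) {
    if (length(li[[g]])) cat("  /", g, ": ", paste(li[[g]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
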