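# Contact-vector tables are tab-separated text: columns id, length,
# label ("native"/"decoy"), the 210 count columns in the canonical pair
# order of contact_type_names(), then any provenance columns.

# enable data.table [] semantics inside this package without attaching it
.datatable.aware <- TRUE

#' Write contact vectors as a TSV table
#'
#' @param x Either a list of `contact_vector`s, or a list with elements
#'   `X` (matrix), `ids`, `lengths` and optionally `labels` (+1/-1) or
#'   `label` strings.
#' @param path Output path.
#' @param label Default class label when `x` carries none
#'   ("native" or "decoy").
#' @param extra Optional data.frame of provenance columns (one row per
#'   vector).
#' @return `path`, invisibly.
#' @export
write_vectors_tsv <- function(x, path, label = "native", extra = NULL) {
  if (is.list(x) && !is.null(x$X)) {
    X <- as.matrix(x$X)
    ids <- x$ids %||% rownames(X)
    lens <- x$lengths %||% rep(NA_integer_, nrow(X))
    labs <- if (!is.null(x$labels)) {
      ifelse(x$labels < 0, "native", "decoy")
    } else {
      rep(label, nrow(X))
    }
  } else {
    X <- do.call(rbind, lapply(x, as.numeric))
    ids <- vapply(x, function(v) as.character(attr(v, "id") %||% ""), "")
    lens <- vapply(x, function(v) as.integer(attr(v, "length")), 0L)
    labs <- rep(label, nrow(X))
  }
  colnames(X) <- contact_type_names()
  tab <- data.table::data.table(id = ids, length = lens, label = labs)
  tab <- cbind(tab, data.table::as.data.table(X))
  if (!is.null(extra)) tab <- cbind(tab, data.table::as.data.table(extra))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read a contact-vector TSV table
#'
#' @param path Path written by [write_vectors_tsv()] (or any table with
#'   the same schema).
#' @return List with `X` (matrix, rownames = ids), `ids`, `lengths`,
#'   `labels` (+1 decoy / -1 native), and `extra` (data.frame of any
#'   provenance columns, or NULL).
#' @export
read_vectors_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t", check.names = FALSE)
  parse_vector_table(tab)
}

parse_vector_table <- function(tab) {
  need <- c("id", "length", "label")
  if (!all(need %in% names(tab))) {
    stop("vector table must have columns ", paste(need, collapse = ", "))
  }
  ct <- contact_type_names()
  if (!all(ct %in% names(tab))) {
    stop("vector table is missing contact-type columns")
  }
  X <- as.matrix(tab[, ct, with = FALSE])
  rownames(X) <- tab$id
  extra_cols <- setdiff(names(tab), c(need, ct))
  list(
    X = X,
    ids = as.character(tab$id),
    lengths = as.integer(tab$length),
    labels = ifelse(tab$label == "native", -1, 1),
    extra = if (length(extra_cols)) as.data.frame(tab[, extra_cols, with = FALSE])
  )
}

#' Stream a contact-vector TSV in chunks
#'
#' @param path TSV path.
#' @param chunk Rows per chunk.
#' @param callback Function called with each parsed chunk (the list
#'   layout of [read_vectors_tsv()]).
#' @return Number of rows streamed, invisibly.
#' @export
stream_vectors_tsv <- function(path, chunk = 4096L, callback) {
  header <- names(data.table::fread(path, sep = "\t", nrows = 0L,
                                    check.names = FALSE))
  skip <- 1L
  total <- 0L
  repeat {
    tab <- data.table::fread(path, sep = "\t", skip = skip, nrows = chunk,
                             header = FALSE, col.names = header,
                             check.names = FALSE)
    if (nrow(tab) == 0L) break
    callback(parse_vector_table(tab))
    total <- total + nrow(tab)
    skip <- skip + nrow(tab)
    if (nrow(tab) < chunk) break
  }
  invisible(total)
}

#' Serialize a length model as JSON (keys a, b)
#' @param model A `length_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_length_model <- function(model, path) {
  jsonlite::write_json(list(a = num_str(model$a), b = num_str(model$b)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a length model from JSON
#' @param path JSON path with keys `a` and `b`.
#' @return A `length_model`.
#' @export
read_length_model <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(a = as.numeric(x$a), b = as.numeric(x$b),
                 se = c(NA_real_, NA_real_), n = NA_integer_),
            class = "length_model")
}

# doubles round-trip exactly through %.17g strings
num_str <- function(x) sprintf("%.17g", as.numeric(x))

#' Save a fitness model container
#'
#' Single-file JSON container: metadata (kernel width, label convention,
#' provenance) plus the dense arrays Abar, Dbar, u and gamma. Numeric
#' arrays are serialized as full-precision strings so that
#' [load_fitness_model()] restores them value-exactly.
#'
#' @param model A [fitness_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_fitness_model <- function(model, path) {
  obj <- list(
    container = "fitscape-fitness-model",
    format_version = 1L,
    metadata = list(
      kernel = list(family = "gaussian", mu = num_str(model$kernel$mu)),
      label_convention = "native=-1,decoy=+1; fitness<0 => native-like",
      provenance = model$provenance
    ),
    basis = list(
      m_bar = nrow(model$basis$X),
      dim = ncol(model$basis$X),
      ids = model$basis$ids,
      labels = as.integer(model$basis$labels),
      X = num_str(as.numeric(t(model$basis$X))) # row-major
    ),
    coefficients = list(u = num_str(model$u), gamma = num_str(model$gamma)),
    length_model = if (!is.null(model$length_model)) {
      list(a = num_str(model$length_model$a), b = num_str(model$length_model$b))
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a fitness model container
#' @param path Path written by [save_fitness_model()].
#' @return A [fitness_model()].
#' @export
load_fitness_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "fitscape-fitness-model")) {
    stop("not a fitness-model container: ", path)
  }
  X <- matrix(as.numeric(obj$basis$X), nrow = obj$basis$m_bar,
              ncol = obj$basis$dim, byrow = TRUE)
  basis <- basis_set(X, labels = as.numeric(obj$basis$labels),
                     ids = obj$basis$ids)
  lm_fit <- NULL
  if (!is.null(obj$length_model)) {
    lm_fit <- structure(list(a = as.numeric(obj$length_model$a),
                             b = as.numeric(obj$length_model$b),
                             se = c(NA_real_, NA_real_), n = NA_integer_),
                        class = "length_model")
  }
  fitness_model(
    basis = basis,
    u = as.numeric(obj$coefficients$u),
    gamma = as.numeric(obj$coefficients$gamma),
    kernel = kernel_params(as.numeric(obj$metadata$kernel$mu)),
    length_model = lm_fit,
    provenance = as.list(obj$metadata$provenance)
  )
}
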