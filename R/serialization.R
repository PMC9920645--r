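#' Serialize an ELM model to JSON
#'
#' Writes `{n_features, n_hidden, n_classes, activation, seed, W, b, beta,
#' class_names}` with `W` and `beta` as row-major nested arrays at full
#' precision; the round trip is loss-bounded to 1e-12 relative.
#'
#' @param model An `elm_model` from [train_elm()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_elm_model <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  obj <- list(
    n_features = model$n_features, n_hidden = model$n_hidden,
    n_classes = model$n_classes, activation = model$activation,
    seed = model$seed,
    W = apply(model$W, 1L, identity, simplify = FALSE),
    b = model$b,
    beta = apply(model$beta, 1L, identity, simplify = FALSE),
    class_names = model$class_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rebuild a matrix from JSON row-major nested arrays; jsonlite may have
# simplified them to a matrix (already row-oriented) or a bare vector.
json_matrix <- function(x, nr, nc) {
  if (is.list(x)) matrix(as.numeric(unlist(x)), nr, nc, byrow = TRUE)
  else matrix(as.numeric(x), nr, nc)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      W = json_matrix(raw$W, raw$n_features, raw$n_hidden),
      b = as.numeric(raw$b),
      beta = json_matrix(raw$beta, raw$n_hidden, raw$n_classes),
      activation = raw$activation, seed = as.integer(raw$seed),
      n_features = as.integer(raw$n_features),
      n_hidden = as.integer(raw$n_hidden),
      n_classes = as.integer(raw$n_classes),
      class_names = raw$class_names
    ),
    class = "elm_model"
  )
}

# Run-length encoding of a 0/1 vector as alternating run lengths starting
# with the length of the initial 0-run (possibly 0).
rle_encode_bits <- function(bits) {
  r <- rle(as.integer(bits))
  lens <- r$lengths
  if (r$values[1] == 1L) lens <- c(0L, lens)
  as.integer(lens)
}

rle_decode_bits <- function(lens, n) {
  vals <- rep_len(c(0L, 1L), length(lens))
  out <- rep(vals, lens)
  stopifnot(length(out) == n)
  out
}

#' Serialize a pruned KTGEL model to JSON
#'
#' Extends the ELM schema with the run-length-encoded weight mask and the
#' active node/feature index lists.
#'
#' @param model A `ktgel_model` from [train_ktgel()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_ktgel_model <- function(model, path) {
  stopifnot(inherits(model, "ktgel_model"))
  obj <- list(
    n_features = model$n_features,
    n_hidden_initial = model$n_hidden_initial,
    n_classes = model$n_classes, activation = model$activation,
    seed = model$seed,
    W = apply(model$W, 1L, identity, simplify = FALSE),
    b = model$b,
    beta = apply(model$beta, 1L, identity, simplify = FALSE),
    class_names = model$class_names,
    mask_rle = rle_encode_bits(as.vector(model$mask)),
    active_nodes = model$active_nodes,
    active_features = model$active_features,
    fitness = model$fitness
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ktgel_model
#' @export
read_ktgel_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(raw$n_features)
  L0 <- as.integer(raw$n_hidden_initial)
  mask <- matrix(rle_decode_bits(as.integer(raw$mask_rle), n * L0), n, L0)
  n_active <- length(raw$active_nodes)
  structure(
    list(
      W = json_matrix(raw$W, n, n_active),
      b = as.numeric(raw$b),
      beta = json_matrix(raw$beta, n_active, as.integer(raw$n_classes)),
      activation = raw$activation, mask = mask,
      active_nodes = as.integer(raw$active_nodes),
      active_features = as.integer(raw$active_features),
      n_features = n, n_hidden_initial = L0,
      n_classes = as.integer(raw$n_classes),
      class_names = raw$class_names,
      fitness = as.numeric(raw$fitness),
      history = NULL, seed = as.integer(raw$seed)
    ),
    class = "ktgel_model"
  )
}
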