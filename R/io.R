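#' Save and load model bundles
#'
#' A fitted model is persisted as a self-describing directory of plain
#' files: `genome.json` (architecture), `weights.txt` and `bn_state.txt`
#' (flat parameter vectors, one value per line, full precision),
#' `scaler.json` (RT min/max) and `manifest.json` (alphabet, encoding
#' length, provenance).  Directories rather than archives keep bundles
#' diff-able.
#'
#' @param model a fitted [rtnet()].
#' @param path bundle directory (created if absent).
#' @return `save_rt_model()`: the path, invisibly; `load_rt_model()`: the
#'   restored `rtnet`.
#' @export
save_rt_model <- function(model, path) {
  stopifnot(inherits(model, "rtnet"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(as.character(genome_to_json(model$genome)),
             file.path(path, "genome.json"))
  writeLines(sprintf("%.17g", model$weights),
             file.path(path, "weights.txt"))
  writeLines(sprintf("%.17g", model$bn_state),
             file.path(path, "bn_state.txt"))
  writeLines(as.character(jsonlite::toJSON(
    list(rt_min = unname(model$scaler[[1]]),
         rt_max = unname(model$scaler[[2]])),
    auto_unbox = TRUE, digits = NA)), file.path(path, "scaler.json"))
  prov <- model$provenance
  prov$history <- NULL
  writeLines(as.character(jsonlite::toJSON(
    list(alphabet_mods = as.list(model$alphabet$mods),
         fixed_length = model$fixed_length,
         provenance = prov),
    auto_unbox = TRUE, digits = NA)), file.path(path, "manifest.json"))
  invisible(path)
}

#' @rdname save_rt_model
#' @export
load_rt_model <- function(path) {
  manifest <- jsonlite::fromJSON(file.path(path, "manifest.json"),
                                 simplifyDataFrame = FALSE)
  mods <- unlist(manifest$alphabet_mods)
  alphabet <- if (length(mods)) rt_alphabet(mods) else rt_alphabet(c())
  genome <- genome_from_json(
    paste(readLines(file.path(path, "genome.json")), collapse = ""))
  scaler_raw <- jsonlite::fromJSON(file.path(path, "scaler.json"))
  scaler <- structure(c(rt_min = scaler_raw$rt_min,
                        rt_max = scaler_raw$rt_max), class = "rt_scaler")
  structure(list(
    genome = genome,
    weights = as.numeric(readLines(file.path(path, "weights.txt"))),
    bn_state = as.numeric(readLines(file.path(path, "bn_state.txt"))),
    scaler = scaler,
    alphabet = alphabet,
    fixed_length = as.integer(manifest$fixed_length),
    provenance = manifest$provenance),
    class = "rtnet")
}
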