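cohort_columns <- c("participant_id", "k10_total", "psqi_total", "scs_total",
                    "pa_score", "eat_score", "mcqa_total", "maas_total",
                    "bis_total", "qol_physical", "qol_social", "qol_psych",
                    "cyberstrife")

#' Read a raw cohort CSV
#'
#' Cohort files are comma-separated UTF-8 with a mandatory header and `.`
#' decimals. Required columns: `participant_id`, `k10_total`, `psqi_total`,
#' `scs_total`, `pa_score`, `eat_score`, `mcqa_total`, `maas_total`,
#' `bis_total`, `qol_physical`, `qol_social`, `qol_psych`, `cyberstrife`
#' (true/false, yes/no or 0/1). Unparseable score cells become `NA` with a
#' warning naming the row (complete-case exclusion happens later, in
#' [discretize_cohort()]); scores outside their instrument's theoretical
#' range are an error naming the row.
#'
#' @param path Path to a CSV file.
#' @param ranges Optional range overrides, as in
#'   [default_discretization_rules()].
#' @return Raw cohort data frame.
#' @export
read_cohort_csv <- function(path, ranges = list()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(cohort_columns, names(raw))
  if (length(missing)) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rules <- default_discretization_rules(ranges)
  score_cols <- setdiff(cohort_columns, c("participant_id", "cyberstrife"))
  out <- data.frame(participant_id = raw$participant_id,
                    stringsAsFactors = FALSE)
  rng <- stats::setNames(lapply(rules, function(r)
    c(r$scale_min, r$scale_max)),
    vapply(rules, `[[`, character(1), "column"))
  for (col in score_cols) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad_parse <- which(is.na(x) & nzchar(trimws(raw[[col]])))
    if (length(bad_parse)) {
      warning("column '", col, "': unparseable value(s) in data row(s) ",
              paste(bad_parse, collapse = ", "), "; treated as missing",
              call. = FALSE)
    }
    lim <- rng[[col]]
    oob <- which(!is.na(x) & (x < lim[1] | x > lim[2]))
    if (length(oob)) {
      stop("column '", col, "': value ", x[oob[1]], " in data row ", oob[1],
           " outside theoretical range [", lim[1], ", ", lim[2], "]",
           call. = FALSE)
    }
    out[[col]] <- x
  }
  cb <- tolower(trimws(raw$cyberstrife))
  val <- rep(NA, nrow(raw))
  val[cb %in% c("true", "yes", "1", "t")] <- TRUE
  val[cb %in% c("false", "no", "0", "f")] <- FALSE
  bad <- which(is.na(val) & nzchar(cb))
  if (length(bad)) {
    warning("column 'cyberstrife': unparseable value(s) in data row(s) ",
            paste(bad, collapse = ", "), "; treated as missing",
            call. = FALSE)
  }
  out$cyberstrife <- val
  out
}

#' Write a raw cohort CSV
#'
#' @param raw Raw cohort data frame (the [read_cohort_csv()] dialect).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(raw, path) {
  utils::write.csv(raw[, cohort_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- network YAML ---------------------------------------------------------

#' Write a network (structure + CPTs) to a YAML file
#'
#' The document lists each node with its states, parents and CPT rows (one
#' probability vector per parent-state configuration, parents cycling
#' first-parent-fastest). Probabilities are serialized at full double
#' precision so a read-back is numerically identical.
#'
#' @param pnet A `distress_bn`.
#' @param path Output path.
#' @param name,version Metadata strings stored in the document.
#' @return `path`, invisibly.
#' @seealso [read_network_yaml()]
#' @export
write_network_yaml <- function(pnet, path, name = "distress_bn",
                               version = "1") {
  stopifnot(inherits(pnet, "distress_bn"))
  doc <- list(
    name = name, version = as.character(version),
    nodes = lapply(unname(node_names(pnet$spec)), function(v) {
      nd <- pnet$spec[[v]]
      cpt <- pnet$cpts[[v]]
      k <- length(nd$states)
      m <- matrix(as.numeric(cpt), nrow = k)
      list(name = v, states = as.list(nd$states),
           parents = as.list(nd$parents),
           cpt = lapply(seq_len(ncol(m)), function(j)
             lapply(m[, j], format_probability)))
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

# 17 significant digits: round-trips an IEEE double through text exactly.
# Kept as strings in the document so the YAML emitter cannot re-round them.
format_probability <- function(p) formatC(p, digits = 17, format = "g")

#' Read a network YAML file
#'
#' Parses and validates a document written by [write_network_yaml()] (or
#' by hand): structure invariants (unique names, resolvable parents,
#' acyclicity) and CPT invariants (complete rows summing to 1) are
#' enforced, with errors naming the offending node.
#'
#' @param path Path to the YAML file.
#' @return A `distress_bn`.
#' @export
read_network_yaml <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path,
                               call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$nodes)) stop("network file has no 'nodes' list",
                               call. = FALSE)
  nodes <- lapply(doc$nodes, function(nd)
    bn_node(nd$name, unlist(nd$states),
            parents = as.character(unlist(nd$parents))))
  spec <- bn_spec(nodes)
  cpts <- stats::setNames(lapply(doc$nodes, function(nd) {
    vals <- unlist(nd$cpt)
    nd_spec <- spec[[nd$name]]
    bn_cpt(nd$name, nd_spec$states, vals, nd_spec$parents,
           stats::setNames(lapply(spec[nd_spec$parents], `[[`, "states"),
                           nd_spec$parents))
  }), vapply(doc$nodes, `[[`, character(1), "name"))
  parameterized_network(spec, cpts)
}

# ---- XMLBIF ---------------------------------------------------------------

#' Export a network in XMLBIF 0.3 format
#'
#' Writes the interchange format understood by standard Bayesian-network
#' tools. Table entries follow the common convention: parent
#' configurations enumerated row-major over the GIVEN order (first parent
#' slowest, last parent fastest) and, within each configuration, one
#' probability per OUTCOME in declaration order. XML special characters in
#' names and state labels are escaped by the writer, so labels with
#' spaces or punctuation survive a round trip.
#'
#' @param pnet A `distress_bn`.
#' @param path Output path.
#' @param name Network name recorded in the document.
#' @return `path`, invisibly.
#' @seealso [import_xmlbif()]
#' @export
export_xmlbif <- function(pnet, path, name = "distress_bn") {
  stopifnot(inherits(pnet, "distress_bn"))
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  net <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(net, "NAME", name)
  for (v in node_names(pnet$spec)) {
    var <- xml2::xml_add_child(net, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(var, "NAME", v)
    for (s in pnet$spec[[v]]$states) xml2::xml_add_child(var, "OUTCOME", s)
  }
  for (v in node_names(pnet$spec)) {
    nd <- pnet$spec[[v]]
    def <- xml2::xml_add_child(net, "DEFINITION")
    xml2::xml_add_child(def, "FOR", v)
    for (p in nd$parents) xml2::xml_add_child(def, "GIVEN", p)
    cpt <- pnet$cpts[[v]]
    k <- length(nd$states)
    m <- matrix(as.numeric(cpt), nrow = k)
    # columns are first-parent-fastest; XMLBIF wants first parent slowest
    if (length(nd$parents) > 1L) {
      card <- vapply(pnet$spec[nd$parents], function(x) length(x$states),
                     integer(1))
      perm <- order_configs_first_slowest(card)
      m <- m[, perm, drop = FALSE]
    }
    tab <- paste(vapply(as.numeric(m), function(p)
      formatC(p, digits = 17, format = "g"), character(1)),
      collapse = " ")
    xml2::xml_add_child(def, "TABLE", tab)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# Map column order from first-parent-fastest (native) to an enumeration
# with the first parent slowest: returns the permutation of native columns.
order_configs_first_slowest <- function(card) {
  grid <- expand.grid(lapply(card, seq_len), KEEP.OUT.ATTRS = FALSE)
  # native linear index of each row when the first parent varies fastest
  mult <- cumprod(c(1, card[-length(card)]))
  native <- as.integer(as.matrix(grid) %*% mult - sum(mult) + 1)
  # enumerate target order: last index fastest = reverse-order expand.grid
  target <- do.call(order, as.list(grid[, seq_along(card), drop = FALSE]))
  native[target]
}

#' Import a network from XMLBIF 0.3
#'
#' Inverse of [export_xmlbif()]; validates structure and CPTs on load.
#'
#' @param path Path to an XMLBIF file.
#' @return A `distress_bn`.
#' @export
import_xmlbif <- function(path) {
  if (!file.exists(path)) stop("XMLBIF file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  vars <- xml2::xml_find_all(doc, ".//VARIABLE")
  states <- list()
  for (v in vars) {
    nm <- xml2::xml_text(xml2::xml_find_first(v, "./NAME"))
    states[[nm]] <- xml2::xml_text(xml2::xml_find_all(v, "./OUTCOME"))
  }
  defs <- xml2::xml_find_all(doc, ".//DEFINITION")
  nodes <- list()
  tables <- list()
  parents_of <- list()
  for (d in defs) {
    nm <- xml2::xml_text(xml2::xml_find_first(d, "./FOR"))
    given <- xml2::xml_text(xml2::xml_find_all(d, "./GIVEN"))
    tab <- as.numeric(strsplit(trimws(
      xml2::xml_text(xml2::xml_find_first(d, "./TABLE"))), "\\s+")[[1]])
    nodes[[nm]] <- bn_node(nm, states[[nm]], parents = given)
    parents_of[[nm]] <- given
    tables[[nm]] <- tab
  }
  spec <- bn_spec(unname(nodes))
  cpts <- stats::setNames(lapply(names(nodes), function(nm) {
    parents <- parents_of[[nm]]
    k <- length(states[[nm]])
    m <- matrix(tables[[nm]], nrow = k)
    if (length(parents) > 1L) {
      card <- vapply(states[parents], length, integer(1))
      perm <- order_configs_first_slowest(card)
      m[, perm] <- m  # invert the export permutation
    }
    bn_cpt(nm, states[[nm]], m, parents,
           stats::setNames(states[parents], parents))
  }), names(nodes))
  parameterized_network(spec, cpts)
}

# ---- run configuration ----------------------------------------------------

#' Read a run-configuration YAML file
#'
#' A run config ties a pipeline invocation together: input paths, optional
#' instrument-range overrides, scenario definitions, seed and output
#' directory. The schema is validated on load and referenced input files
#' must exist.
#'
#' Fields: `cohort_csv` (path), optional `network_yaml` (path), optional
#' `ranges` (named list of `[min, max]`), optional `scenarios` (named list
#' of `{node: state}` maps), optional `seed` (integer, default 1),
#' optional `out_dir` (default `"."`).
#'
#' @param path Path to the YAML config.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cohort_csv)) {
    stop("config must name a 'cohort_csv'", call. = FALSE)
  }
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  cfg$cohort_csv <- resolve(cfg$cohort_csv)
  if (!file.exists(cfg$cohort_csv)) {
    stop("cohort_csv does not exist: ", cfg$cohort_csv, call. = FALSE)
  }
  if (!is.null(cfg$network_yaml)) {
    cfg$network_yaml <- resolve(cfg$network_yaml)
    if (!file.exists(cfg$network_yaml)) {
      stop("network_yaml does not exist: ", cfg$network_yaml, call. = FALSE)
    }
  }
  if (!is.null(cfg$ranges)) {
    ok <- vapply(cfg$ranges, function(r) length(r) == 2 && r[[1]] < r[[2]],
                 logical(1))
    if (!all(ok)) stop("each range override must be [min, max] with min < max",
                       call. = FALSE)
    cfg$ranges <- lapply(cfg$ranges, function(r) c(r[[1]], r[[2]]))
  }
  if (!is.null(cfg$scenarios)) {
    cfg$scenarios <- lapply(cfg$scenarios, function(s)
      unlist(s))
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  class(cfg) <- "run_config"
  cfg
}
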