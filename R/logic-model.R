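## Logic models: named nodes, each with an update rule (bool_expr), an
## activation propensity p_a, a degradation propensity p_d, a role
## (input/internal/readout) and a compartment tag (cart/tumor/interface).

NODE_ROLES <- c("input", "internal", "readout")
NODE_COMPARTMENTS <- c("cart", "tumor", "interface")

#' Create a node specification
#'
#' @param name node name (identifier).
#' @param rule a [bool_expr][bool_const] or a rule string (parsed on the fly).
#' @param p_a activation propensity: probability that a node whose rule is
#'   satisfied while the node is OFF switches ON in an iteration.
#' @param p_d degradation propensity: probability that a node whose rule is
#'   unsatisfied while the node is ON switches OFF in an iteration.
#' @param role one of `"input"`, `"internal"`, `"readout"`.
#' @param compartment one of `"cart"`, `"tumor"`, `"interface"`.
#' @return object of class `node_spec`.
#' @export
node_spec <- function(name, rule, p_a = 0.5, p_d = 0.05,
                      role = "internal", compartment = "cart") {
  if (is.character(rule)) rule <- parse_expression(rule)
  stopifnot(is_bool_expr(rule))
  if (!grepl("^[A-Za-z][A-Za-z0-9]*$", name)) {
    stop("invalid node name: ", deparse(name), call. = FALSE)
  }
  if (!is.numeric(p_a) || length(p_a) != 1 || is.na(p_a) || p_a < 0 || p_a > 1) {
    stop("p_a must be a probability in [0,1] for node ", name, call. = FALSE)
  }
  if (!is.numeric(p_d) || length(p_d) != 1 || is.na(p_d) || p_d < 0 || p_d > 1) {
    stop("p_d must be a probability in [0,1] for node ", name, call. = FALSE)
  }
  role <- match.arg(role, NODE_ROLES)
  compartment <- match.arg(compartment, NODE_COMPARTMENTS)
  structure(list(name = name, rule = rule, p_a = as.numeric(p_a),
                 p_d = as.numeric(p_d), role = role, compartment = compartment),
            class = "node_spec")
}

#' Assemble a logic model from node specifications
#'
#' @param nodes list of [node_spec()] objects (declaration order is kept).
#' @param name model name.
#' @param metadata named list of free-form annotations.
#' @param validate run [validate_model()] and stop on problems (default TRUE).
#' @return object of class `logic_model`: fields `name`, `nodes` (named list,
#'   in declaration order) and `metadata`.
#' @export
logic_model <- function(nodes, name = "model", metadata = list(),
                        validate = TRUE) {
  stopifnot(is.list(nodes))
  nms <- vapply(nodes, function(n) n$name, character(1))
  names(nodes) <- nms
  m <- structure(list(name = name, nodes = nodes, metadata = metadata),
                 class = "logic_model")
  if (validate) {
    problems <- validate_model(m)
    if (length(problems)) {
      stop("invalid logic model:\n  - ", paste(problems, collapse = "\n  - "),
           call. = FALSE)
    }
  }
  m
}

#' @export
print.logic_model <- function(x, ...) {
  cat(sprintf("<logic_model> %s: %d nodes (%d input, %d readout)\n",
              x$name, length(x$nodes),
              sum(node_roles(x) == "input"), sum(node_roles(x) == "readout")))
  invisible(x)
}

#' Node name / role / compartment accessors
#' @param model a [logic_model()].
#' @return character vectors in declaration order.
#' @export
node_names <- function(model) {
  vapply(model$nodes, function(n) n$name, character(1), USE.NAMES = FALSE)
}

#' @rdname node_names
#' @export
node_roles <- function(model) {
  stats::setNames(vapply(model$nodes, function(n) n$role, character(1)),
                  node_names(model))
}

#' @rdname node_names
#' @export
node_compartments <- function(model) {
  stats::setNames(vapply(model$nodes, function(n) n$compartment, character(1)),
                  node_names(model))
}

#' @rdname node_names
#' @export
input_nodes <- function(model) names(which(node_roles(model) == "input"))

#' @rdname node_names
#' @export
readout_nodes <- function(model) names(which(node_roles(model) == "readout"))

#' Validate a logic model
#'
#' Checks name uniqueness, propensity ranges, that every variable referenced
#' by any rule names a defined node, that inputs carry constant rules, and
#' that no node is both input and readout.
#'
#' @param model a [logic_model()].
#' @return character vector of problems; empty when the model is valid.
#' @export
validate_model <- function(model) {
  problems <- character(0)
  if (!length(model$nodes)) {
    return("model has no nodes")
  }
  nms <- node_names(model)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate node name(s): ",
                                   paste(dup, collapse = ", ")))
  }
  for (n in model$nodes) {
    if (n$p_a < 0 || n$p_a > 1 || is.na(n$p_a)) {
      problems <- c(problems, paste0("node ", n$name, ": p_a out of [0,1]"))
    }
    if (n$p_d < 0 || n$p_d > 1 || is.na(n$p_d)) {
      problems <- c(problems, paste0("node ", n$name, ": p_d out of [0,1]"))
    }
    unresolved <- setdiff(expression_vars(n$rule), nms)
    if (length(unresolved)) {
      problems <- c(problems,
                    paste0("node ", n$name, ": rule references undefined node(s): ",
                           paste(unresolved, collapse = ", ")))
    }
    if (n$role == "input" && n$rule$kind != "const") {
      problems <- c(problems,
                    paste0("node ", n$name,
                           ": input nodes must carry a constant rule (0 or 1)"))
    }
  }
  problems
}

## ---------------------------------------------------------------------------
## Plain-text model format, line oriented:
##   @model <name>                       (optional header)
##   NAME = EXPR [, pa=<f>] [, pd=<f>] [, role=<r>] [, compartment=<c>]
## '#' starts a comment; blank lines ignored. The Boolean grammar contains no
## commas, so commas separate the rule from the key=value attributes.

#' Load a logic model from its plain-text format
#'
#' @param source path to a model file, or the model text itself (anything
#'   containing a newline or an `=` that is not an existing file is treated
#'   as text).
#' @param default_p_a,default_p_d propensities applied to nodes that do not
#'   set their own.
#' @param aliases named character vector mapping accepted alternative node
#'   names to canonical ones (applied to both definitions and references).
#' @return a validated [logic_model()].
#' @export
load_model <- function(source, default_p_a = 0.5, default_p_d = 0.05,
                       aliases = character(0)) {
  stopifnot(is.character(source), length(source) == 1L)
  if (file.exists(source) && !grepl("\n", source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- strsplit(source, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  model_name <- "model"
  nodes <- list()
  problems <- character(0)

  apply_alias <- function(text) {
    for (a in names(aliases)) {
      text <- gsub(paste0("\\b", a, "\\b"), aliases[[a]], text)
    }
    text
  }

  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln)) next
    if (grepl("^@model\\b", ln)) {
      model_name <- trimws(sub("^@model", "", ln))
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) {
      problems <- c(problems, sprintf("line %d: expected 'NAME = EXPR'", k))
      next
    }
    nm <- trimws(substr(ln, 1L, eq - 1L))
    rhs <- substr(ln, eq + 1L, nchar(ln))
    pieces <- strsplit(rhs, ",", fixed = TRUE)[[1L]]
    rule_text <- trimws(pieces[1L])
    attrs <- list(pa = default_p_a, pd = default_p_d,
                  role = "internal", compartment = "cart")
    ok <- TRUE
    for (piece in pieces[-1L]) {
      kv <- strsplit(piece, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) {
        problems <- c(problems, sprintf("line %d: malformed attribute '%s'",
                                        k, trimws(piece)))
        ok <- FALSE
        next
      }
      key <- trimws(kv[1L]); val <- trimws(kv[2L])
      if (key %in% c("pa", "pd")) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) {
          problems <- c(problems,
                        sprintf("line %d: malformed propensity %s=%s", k, key, val))
          ok <- FALSE
        } else attrs[[key]] <- num
      } else if (key %in% c("role", "compartment")) {
        attrs[[key]] <- val
      } else {
        problems <- c(problems, sprintf("line %d: unknown attribute '%s'", k, key))
        ok <- FALSE
      }
    }
    if (!ok) next
    nm <- apply_alias(nm)
    spec <- tryCatch(
      node_spec(nm, apply_alias(rule_text), p_a = attrs$pa, p_d = attrs$pd,
                role = attrs$role, compartment = attrs$compartment),
      error = function(e) {
        problems <<- c(problems, sprintf("line %d (%s): %s", k, nm,
                                         conditionMessage(e)))
        NULL
      })
    if (!is.null(spec)) nodes[[length(nodes) + 1L]] <- spec
  }

  if (!length(nodes) && !length(problems)) problems <- "model has no nodes"
  m <- structure(list(name = model_name, nodes = nodes, metadata = list()),
                 class = "logic_model")
  if (length(nodes)) names(m$nodes) <- vapply(nodes, `[[`, character(1), "name")
  problems <- c(problems, if (length(nodes)) validate_model(m) else character(0))
  if (length(problems)) {
    stop("invalid logic model:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  m
}

#' Serialize a logic model to its plain-text format
#'
#' `load_model(save_model(m))` reproduces `m` structurally (same nodes, rules,
#' propensities, roles and compartments). Metadata is not serialized.
#'
#' @param model a [logic_model()].
#' @param path optional output file; when NULL the text is returned.
#' @return the model text, invisibly when written to `path`.
#' @export
save_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "logic_model"))
  lines <- c(paste0("@model ", model$name),
             vapply(model$nodes, function(n) {
               sprintf("%s = %s, pa=%s, pd=%s, role=%s, compartment=%s",
                       n$name, format_expression(n$rule),
                       format(n$p_a, digits = 17), format(n$p_d, digits = 17),
                       n$role, n$compartment)
             }, character(1), USE.NAMES = FALSE))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Dependency graph of a logic model
#'
#' Builds the directed regulator-to-target graph: an edge `u -> v` exists iff
#' variable `u` appears in `v`'s rule. Each edge carries a `sign` attribute:
#' `"activating"` when every occurrence of the regulator sits under an even
#' number of negations, `"inhibitory"` when under an odd number, `"dual"` for
#' mixed occurrences.
#'
#' @param model a validated [logic_model()].
#' @return an [igraph][igraph::graph_from_data_frame] directed graph whose
#'   vertices are all model nodes.
#' @export
dependency_graph <- function(model) {
  stopifnot(inherits(model, "logic_model"))
  edges <- list()
  for (n in model$nodes) {
    signs <- expression_signs(n$rule)
    for (reg in names(signs)) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = reg, to = n$name, sign = signs[[reg]],
                   stringsAsFactors = FALSE)
    }
  }
  edf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), sign = character(0))
  igraph::graph_from_data_frame(edf, directed = TRUE,
                                vertices = data.frame(name = node_names(model)))
}

#' Export rules in BoolNet "targets, factors" CSV form
#'
#' Interoperability export for attractor-analysis tools. Lossy: propensities,
#' roles and compartments are dropped (the format carries only the logic).
#'
#' @param model a [logic_model()].
#' @param path optional output file.
#' @return character vector of lines, invisibly when written to `path`.
#' @export
export_boolnet <- function(model, path = NULL) {
  stopifnot(inherits(model, "logic_model"))
  lines <- c("targets, factors",
             vapply(model$nodes, function(n) {
               paste0(n$name, ", ", format_expression(n$rule))
             }, character(1), USE.NAMES = FALSE))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Activatable closure: which nodes can ever switch ON
#'
#' Computes the least fixed point of "a node is activatable if it starts ON
#' or its rule can evaluate TRUE given that only activatable nodes may be 1"
#' (any node may be 0). Nodes outside the closure are structural zeros: their
#' activity is exactly 0 at every iteration of every replicate. Knocked-out
#' nodes are excluded from the closure regardless of their rule.
#'
#' @param model a [logic_model()].
#' @param initially_on names of nodes whose initial state is (or may be) 1.
#' @param knocked_out names of nodes clamped OFF (forced 0, p_a = 0).
#' @return character vector of activatable node names.
#' @export
activatable_closure <- function(model, initially_on = character(0),
                                knocked_out = character(0)) {
  stopifnot(inherits(model, "logic_model"))
  nms <- node_names(model)
  on_set <- setdiff(intersect(initially_on, nms), knocked_out)
  can_true <- function(e, S) {
    switch(e$kind,
      const = e$value == 1L,
      var = e$name %in% S,
      # any node can be 0 (all start 0 or may fail a coin flip), so a negated
      # literal is always satisfiable; this over-approximates activatability,
      # keeping "outside the closure => identically 0" sound
      not = can_false(e$children[[1L]], S),
      and = all(vapply(e$children, can_true, logical(1), S = S)),
      or = any(vapply(e$children, can_true, logical(1), S = S))
    )
  }
  can_false <- function(e, S) {
    switch(e$kind,
      const = e$value == 0L,
      var = TRUE,
      not = can_true(e$children[[1L]], S),
      and = any(vapply(e$children, can_false, logical(1), S = S)),
      or = all(vapply(e$children, can_false, logical(1), S = S))
    )
  }
  S <- on_set
  repeat {
    added <- FALSE
    for (n in model$nodes) {
      if (n$name %in% S || n$name %in% knocked_out) next
      if (can_true(n$rule, S)) {
        S <- c(S, n$name)
        added <- TRUE
      }
    }
    if (!added) break
  }
  intersect(nms, S)  # declaration order
}
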