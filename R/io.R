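#' Read / write networks in JSON or BIF format
#'
#' The canonical JSON schema is a list of node records:
#' `{"nodes":[{"name":..,"states":[..],"parents":[..],"cpt":[[..],..]},..]}`
#' where `cpt` (optional) is a `q_i x r_i` array of rows in configuration
#' order. BIF (Bayesian Interchange Format) is supported for
#' interoperability with other Bayesian-network tools.
#'
#' @param path File path.
#' @param format `"json"` or `"bif"`; inferred from the file extension when
#'   omitted.
#' @return `read_network()`: a [bn_network()]; `write_network()`: `path`,
#'   invisibly.
#' @export
read_network <- function(path, format = c("auto", "json", "bif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bif$", path, ignore.case = TRUE)) "bif" else "json"
  }
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "json") read_network_json(path) else read_network_bif(path)
}

#' @rdname read_network
#' @param net A [bn_network()].
#' @export
write_network <- function(net, path, format = c("auto", "json", "bif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bif$", path, ignore.case = TRUE)) "bif" else "json"
  }
  if (format == "json") write_network_json(net, path)
  else write_network_bif(net, path)
  invisible(path)
}

read_network_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- spec$nodes
  if (is.null(recs)) abort("JSON network must have a 'nodes' array")
  nm <- vapply(recs, function(x) x$name, character(1))
  states <- lapply(recs, function(x) as.character(unlist(x$states)))
  parents <- lapply(recs, function(x) as.character(unlist(x$parents)))
  net <- bn_network(
    nodes = nm,
    parents = setNames(parents, nm),
    cardinalities = setNames(lengths(states), nm),
    states = setNames(states, nm)
  )
  has_cpt <- vapply(recs, function(x) !is.null(x$cpt), logical(1))
  if (all(has_cpt)) {
    mats <- setNames(lapply(recs, function(x) {
      do.call(rbind, lapply(x$cpt, function(row) as.numeric(unlist(row))))
    }), nm)
    net <- set_cpt(net, matrices_to_cpt(net, mats))
  } else if (any(has_cpt)) {
    warn("some nodes lack a cpt entry; parameters dropped")
  }
  net
}

write_network_json <- function(net, path) {
  mats <- if (!is.null(net$cpt)) cpt_to_matrices(net, net$cpt)
  recs <- lapply(net$nodes, function(nd) {
    rec <- list(name = nd, states = net$states[[nd]],
                parents = net$parents[[nd]])
    if (!is.null(mats)) {
      rec$cpt <- lapply(seq_len(nrow(mats[[nd]])),
                        function(j) mats[[nd]][j, ])
    }
    rec
  })
  jsonlite::write_json(list(nodes = recs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

# --- BIF ------------------------------------------------------------------

write_network_bif <- function(net, path) {
  lines <- c("network camap {", "}")
  for (nd in net$nodes) {
    lines <- c(lines,
      paste0("variable ", nd, " {"),
      paste0("  type discrete [ ", net$cardinalities[[nd]], " ] { ",
             paste(net$states[[nd]], collapse = ", "), " };"),
      "}")
  }
  mats <- if (!is.null(net$cpt)) cpt_to_matrices(net, net$cpt)
  if (!is.null(mats)) {
    for (nd in net$nodes) {
      ps <- net$parents[[nd]]
      if (!length(ps)) {
        lines <- c(lines,
          paste0("probability ( ", nd, " ) {"),
          paste0("  table ", paste(format(mats[[nd]][1, ], digits = 17),
                                   collapse = ", "), ";"),
          "}")
      } else {
        body <- vapply(seq_len(net$q[[nd]]), function(j) {
          sts <- parent_config(net, nd, j)
          lab <- paste(vapply(names(sts),
                              function(p) net$states[[p]][sts[[p]]],
                              character(1)), collapse = ", ")
          paste0("  (", lab, ") ",
                 paste(format(mats[[nd]][j, ], digits = 17),
                       collapse = ", "), ";")
        }, character(1))
        lines <- c(lines,
          paste0("probability ( ", nd, " | ", paste(ps, collapse = ", "),
                 " ) {"),
          body, "}")
      }
    }
  }
  writeLines(lines, path)
}

read_network_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)

  var_pat <- "variable\\s+(\\S+)\\s*\\{[^}]*type\\s+discrete\\s*\\[\\s*(\\d+)\\s*\\]\\s*\\{([^}]*)\\}\\s*;[^}]*\\}"
  vm <- gregexpr(var_pat, txt, perl = TRUE)
  vmatch <- regmatches(txt, vm)[[1]]
  if (!length(vmatch)) abort("no variable blocks found in BIF file")
  nm <- character(0); states <- list()
  for (blk in vmatch) {
    g <- regmatches(blk, regexec(var_pat, blk, perl = TRUE))[[1]]
    nm <- c(nm, g[2])
    states[[g[2]]] <- trimws(strsplit(g[4], ",")[[1]])
  }

  prob_pat <- "probability\\s*\\(\\s*([^)|]+?)\\s*(\\|\\s*([^)]*))?\\)\\s*\\{([^}]*)\\}"
  pm <- gregexpr(prob_pat, txt, perl = TRUE)
  pmatch <- regmatches(txt, pm)[[1]]
  parents <- setNames(rep(list(character()), length(nm)), nm)
  rows <- list()
  for (blk in pmatch) {
    g <- regmatches(blk, regexec(prob_pat, blk, perl = TRUE))[[1]]
    child <- trimws(g[2])
    pset <- if (nzchar(trimws(g[4]))) trimws(strsplit(g[4], ",")[[1]])
            else character(0)
    parents[[child]] <- pset
    rows[[child]] <- g[5]
  }

  net <- bn_network(nodes = nm, parents = parents,
                    cardinalities = setNames(lengths(states), nm),
                    states = states)
  if (any(nzchar(unlist(rows)))) {
    mats <- list()
    for (nd in nm) {
      body <- rows[[nd]]
      q <- net$q[[nd]]; r <- net$cardinalities[[nd]]
      m <- matrix(NA_real_, q, r)
      if (!length(net$parents[[nd]])) {
        tb <- regmatches(body, regexec("table([^;]*);", body))[[1]][2]
        m[1, ] <- as.numeric(trimws(strsplit(tb, ",")[[1]]))
      } else {
        ent_pat <- "\\(([^)]*)\\)\\s*([^;]*);"
        ents <- regmatches(body, gregexpr(ent_pat, body, perl = TRUE))[[1]]
        for (e in ents) {
          g <- regmatches(e, regexec(ent_pat, e, perl = TRUE))[[1]]
          labs <- trimws(strsplit(g[2], ",")[[1]])
          ps <- net$parents[[nd]]
          sidx <- setNames(vapply(seq_along(ps), function(m_) {
            match(labs[m_], net$states[[ps[m_]]])
          }, integer(1)), ps)
          if (anyNA(sidx)) abort("unknown parent state label in BIF file")
          j <- config_index(net, nd, sidx)
          m[j, ] <- as.numeric(trimws(strsplit(g[3], ",")[[1]]))
        }
      }
      if (anyNA(m)) abort(paste0("incomplete probability block for '",
                                 nd, "'"))
      mats[[nd]] <- m
    }
    net <- set_cpt(net, matrices_to_cpt(net, mats))
  }
  net
}

#' Read / write a complete discrete dataset as CSV
#'
#' Datasets are tibbles with one integer column per node holding 1-based
#' state indices. On disk they are headered CSVs of state *labels*.
#'
#' @param data Dataset tibble (state indices).
#' @param net The [bn_network()] providing state labels.
#' @param path File path.
#' @return `read_dataset()`: dataset tibble; `write_dataset()`: `path`,
#'   invisibly.
#' @export
write_dataset <- function(data, net, path) {
  lab <- as.data.frame(lapply(net$nodes, function(nd) {
    net$states[[nd]][data[[nd]]]
  }))
  names(lab) <- net$nodes
  utils::write.csv(lab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, net) {
  lab <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(net$nodes, names(lab))
  if (length(missing)) {
    abort(paste0("dataset lacks column(s): ", toString(missing)))
  }
  out <- lapply(net$nodes, function(nd) {
    idx <- match(lab[[nd]], net$states[[nd]])
    if (anyNA(idx)) {
      abort(paste0("unknown state label in column '", nd, "' (record ",
                   which(is.na(idx))[1], ")"))
    }
    idx
  })
  names(out) <- net$nodes
  as_tibble(out)
}
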