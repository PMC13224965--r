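# Newick / extended-Newick input and output.
#
# Dialect: hybrid nodes appear as two occurrences sharing a "#H<k>" tag, the
# occurrence with children being the real node and the other a stub that is
# merged into it.  Edge annotations are ":length:support:gamma"; the support
# field may be empty, and the inheritance probability gamma sits in the third
# field of hybrid-edge annotations ("(b)#H1:0.5::0.3").

#' Parse a Newick gene tree
#'
#' @param text A single Newick statement terminated by `';'`.
#' @return An [ape::phylo] tree.  Rooted input keeps its root, but all quartet
#'   operations in this package treat gene trees as unrooted.
#' @examples
#' parse_newick("((a,b),(c,d));")
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("parse error: not a valid Newick statement")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxon labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy
}

# Cheap syntax scan so errors can name the offending position.
check_newick_syntax <- function(text) {
  if (!nzchar(text)) stop("parse error: empty Newick statement")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("parse error at position %d: unmatched ')'", i))
    }
  }
  if (depth != 0L) stop(sprintf("parse error at position %d: %d unclosed '('",
                                nchar(text), depth))
  if (chars[length(chars)] != ";")
    stop(sprintf("parse error at position %d: statement must end with ';'", nchar(text)))
  invisible(TRUE)
}

#' Parse an extended-Newick network
#'
#' Reads a semi-directed network in extended Newick, where a hybrid node is
#' written as two occurrences sharing a `#H<k>` tag and the inheritance
#' probability is the third colon-separated annotation field.  If gamma is
#' given on only one of the two hybrid edges the other receives `1 - gamma`;
#' if neither carries one, both default to 0.5.  The parsed network must pass
#' [validate_network()].
#'
#' @param text Extended-Newick statement terminated by `';'`.
#' @return A `qcf_network`.
#' @examples
#' net <- parse_enewick("((a,(b)#H1:::0.3),(#H1,(c,d)));")
#' net$h  # 1
#' @export
parse_enewick <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  check_newick_syntax(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  env <- new.env()
  env$pos <- 1L
  env$labels <- character(0)
  env$tags <- character(0)
  env$parent <- integer(0); env$child <- integer(0)
  env$len <- numeric(0); env$gam <- numeric(0)

  peek <- function() if (env$pos <= n) chars[env$pos] else ""
  advance <- function() env$pos <- env$pos + 1L
  fail <- function(msg) stop(sprintf("parse error at position %d: %s", env$pos, msg))

  new_node <- function(label = NA_character_, tag = NA_character_) {
    env$labels <- c(env$labels, label)
    env$tags <- c(env$tags, tag)
    length(env$labels)
  }
  add_edge <- function(p, c, len, gam) {
    env$parent <- c(env$parent, p); env$child <- c(env$child, c)
    env$len <- c(env$len, len); env$gam <- c(env$gam, gam)
  }
  read_token <- function() {
    out <- character(0)
    while (!(peek() %in% c("(", ")", ",", ":", ";", "#", ""))) {
      out <- c(out, peek()); advance()
    }
    paste(out, collapse = "")
  }
  read_fields <- function() {
    f <- c(NA_real_, NA_real_, NA_real_)  # length, support, gamma
    i <- 0L
    while (peek() == ":" && i < 3L) {
      advance(); i <- i + 1L
      tok <- read_token()
      if (nzchar(tok)) {
        val <- suppressWarnings(as.numeric(tok))
        if (is.na(val)) fail(sprintf("non-numeric annotation '%s'", tok))
        f[i] <- val
      }
    }
    f
  }
  parse_clade <- function() {
    kids <- list()
    label <- NA_character_
    if (peek() == "(") {
      advance()
      repeat {
        kids <- c(kids, list(parse_clade()))
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail("expected ',' or ')'")
      }
      label <- read_token()           # internal label, kept but unused
      if (!nzchar(label)) label <- NA_character_
    } else {
      label <- read_token()
      if (!nzchar(label) && peek() != "#") fail("expected a taxon label")
      if (!nzchar(label)) label <- NA_character_
    }
    tag <- NA_character_
    if (peek() == "#") {
      advance()
      tag <- read_token()
      if (!nzchar(tag)) fail("empty hybrid tag after '#'")
    }
    f <- read_fields()
    if (!is.na(tag)) {
      id <- new_node(NA_character_, tag)
      if (!is.na(label) && length(kids) == 0L) {
        # "a#H1" form: hybrid node subtending the leaf 'a'
        leaf <- new_node(label)
        add_edge(id, leaf, NA_real_, NA_real_)
      }
    } else {
      if (length(kids) > 0L) label <- NA_character_
      id <- new_node(label)
    }
    for (k in kids) add_edge(id, k$id, k$len, k$gam)
    list(id = id, len = f[1], gam = f[3])
  }

  top <- parse_clade()
  if (peek() != ";") fail("trailing characters before ';'")

  # merge hybrid stubs
  tags <- env$tags
  for (tg in unique(stats::na.omit(tags))) {
    occ <- which(tags == tg)
    if (length(occ) != 2L)
      stop(sprintf("hybrid tag '#%s' appears %d times (must be exactly 2)",
                   tg, length(occ)))
    outdeg <- tabulate(env$parent, length(env$labels))
    real <- occ[outdeg[occ] > 0L]
    if (length(real) == 0L)
      stop(sprintf("hybrid tag '#%s': neither occurrence has a subtree", tg))
    if (length(real) == 2L)
      stop(sprintf("hybrid tag '#%s': both occurrences have subtrees", tg))
    stub <- setdiff(occ, real)
    env$parent[env$parent == stub] <- real  # defensive; stubs have no children
    env$child[env$child == stub] <- real
  }

  labels <- env$labels
  keep_node <- tabulate(env$parent, length(labels)) +
               tabulate(env$child, length(labels)) > 0L
  keep_node[top$id] <- TRUE
  net <- structure(list(parent = env$parent, child = env$child,
                        length = env$len, gamma = env$gam, labels = labels),
                   class = "qcf_network")
  net <- net_compact(net, rep(TRUE, length(env$parent)))

  # resolve gammas at hybrid nodes
  net <- net_refresh(net)
  for (hn in which(net$indeg == 2L)) {
    es <- which(net$child == hn)
    g <- net$gamma[es]
    if (all(is.na(g))) g <- c(0.5, 0.5)
    else if (is.na(g[1])) g[1] <- 1 - g[2]
    else if (is.na(g[2])) g[2] <- 1 - g[1]
    else if (abs(sum(g) - 1) > 1e-9)
      stop(sprintf("inheritance probabilities at a hybrid node sum to %g, not 1",
                   sum(g)))
    net$gamma[es] <- g
  }
  net <- net_refresh(net)
  if (anyDuplicated(net$taxa))
    stop("duplicate taxon labels: ",
         paste(unique(net$taxa[duplicated(net$taxa)]), collapse = ", "))
  bad <- validate_network(net)
  if (length(bad)) stop("parsed network violates model assumptions: ",
                        paste(bad, collapse = ", "))
  net
}

fmt_num <- function(x) sprintf("%.10g", x)

# Annotation fields for one edge.
enw_fields <- function(len, gam = NA_real_) {
  if (is.na(len) && is.na(gam)) return("")
  if (is.na(gam)) return(paste0(":", fmt_num(len)))
  paste0(":", if (is.na(len)) "" else fmt_num(len), "::", fmt_num(gam))
}

#' Write a network in extended Newick
#'
#' Inverse of [parse_enewick()]: the output round-trips to an isomorphic
#' network (same semi-directed topology, branch lengths and inheritance
#' probabilities).  Each hybrid node appears as two `#H` occurrences; the full
#' subtree is printed under the major parent edge and both hybrid edges are
#' annotated with their gamma.
#'
#' @param net A valid `qcf_network`.
#' @param canonical If `TRUE`, children are ordered by the smallest taxon
#'   label reachable below them and hybrid tags are renumbered in traversal
#'   order, giving a canonical string for a fixed rooted representation.
#' @param annotate If `FALSE`, branch lengths and inheritance probabilities
#'   are omitted (topology-only string).
#' @return A single character string ending in `';'`.
#' @export
write_enewick <- function(net, canonical = FALSE, annotate = TRUE) {
  if (!annotate) { net$length[] <- NA_real_; net$gamma[] <- NA_real_ }
  net <- net_refresh(net)
  N <- length(net$labels)
  hyb_nodes <- which(net$indeg == 2L)
  # min reachable taxon per node, for canonical child ordering
  min_tax <- rep(NA_character_, N)
  ord <- topo_order(net)
  if (is.null(ord)) stop("cannot write a cyclic network")
  for (v in rev(ord)) {
    cand <- net$labels[v]
    for (e in which(net$parent == v)) cand <- c(cand, min_tax[net$child[e]])
    cand <- stats::na.omit(cand)
    if (length(cand)) min_tax[v] <- min(cand)
  }
  build <- function(major_in) {
    tag_env <- new.env()
    assign(".k", 0L, tag_env)
    tag_of <- function(v) {
      key <- as.character(v)
      if (!exists(key, tag_env)) {
        k <- get(".k", tag_env) + 1L
        assign(".k", k, tag_env)
        assign(key, k, tag_env)
      }
      get(key, tag_env)
    }
    rec <- function(v, via) {
      if (net$indeg[v] == 2L) {
        tg <- paste0("#H", tag_of(v))
        gam <- net$gamma[via]
        if (via == major_in[v]) {
          kids <- which(net$parent == v)
          inner <- vapply(kids, function(e) rec(net$child[e], e), "")
          paste0("(", paste(inner, collapse = ","), ")", tg,
                 enw_fields(net$length[via], gam))
        } else {
          paste0(tg, enw_fields(net$length[via], gam))
        }
      } else if (net$outdeg[v] == 0L) {
        paste0(net$labels[v], enw_fields(net$length[via]))
      } else {
        kids <- which(net$parent == v)
        if (canonical) kids <- kids[order(min_tax[net$child[kids]])]
        inner <- vapply(kids, function(e) rec(net$child[e], e), "")
        paste0("(", paste(inner, collapse = ","), ")",
               enw_fields(net$length[via]))
      }
    }
    rt <- net$root
    kids <- which(net$parent == rt)
    if (canonical) kids <- kids[order(min_tax[net$child[kids]])]
    inner <- vapply(kids, function(e) rec(net$child[e], e), "")
    paste0("(", paste(inner, collapse = ","), ");")
  }

  # subtree-printing parent per hybrid: the major edge (larger gamma); at a
  # gamma tie (or omitted gammas) the choice is settled in canonical mode by
  # taking the lexicographically smallest serialization over the tied options
  major_in <- integer(N)
  tied <- integer(0)
  for (hn in hyb_nodes) {
    es <- which(net$child == hn)
    g <- net$gamma[es]
    if (!anyNA(g) && abs(g[1] - g[2]) > 1e-9) {
      major_in[hn] <- es[which.max(g)]
    } else {
      major_in[hn] <- es[1L]
      tied <- c(tied, hn)
    }
  }
  if (!canonical || length(tied) == 0L) return(build(major_in))
  best <- NULL
  for (mask in 0:(2^length(tied) - 1L)) {
    mi <- major_in
    for (j in seq_along(tied)) {
      if (bitwAnd(bitwShiftR(mask, j - 1L), 1L) == 1L) {
        es <- which(net$child == tied[j])
        mi[tied[j]] <- es[2L]
      }
    }
    s <- build(mi)
    if (is.null(best) || s < best) best <- s
  }
  best
}

# Rooted-representation identity up to node renumbering and child order:
# canonical strings compare equal iff topology, lengths and gammas agree.
network_identical <- function(a, b) {
  isTRUE(write_enewick(a, canonical = TRUE) == write_enewick(b, canonical = TRUE))
}
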