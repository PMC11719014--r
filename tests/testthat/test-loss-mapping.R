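status_tbl <- function(tree, pseudo = character(0), indet = character(0)) {
  tibble::tibble(
    taxon = tree$tip.label,
    call = dplyr::case_when(
      tree$tip.label %in% pseudo ~ "pseudogenized",
      tree$tip.label %in% indet ~ "indeterminate",
      TRUE ~ "intact"
    )
  )
}

test_that("all-intact and single-tip cases are handled", {
  tree <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(nrow(dollo_losses(tree, status_tbl(tree))), 0)
  ev <- dollo_losses(tree, status_tbl(tree, pseudo = "D"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$clade_tips[[1]], "D")
  expect_match(narrate_losses(ev)$narrative, "terminal branch of D")
})

test_that("a tribe-like tree places one deep loss after the sister split", {
  tree <- ape::read.tree(
    text = "(((Micromys,(Maxomys,(restA,restB))),out1),out2);"
  )
  st <- status_tbl(tree, pseudo = c("restA", "restB"))
  ev <- dollo_losses(tree, st)
  expect_equal(nrow(ev), 1)
  expect_setequal(ev$clade_tips[[1]], c("restA", "restB"))
  nr <- narrate_losses(ev)
  expect_equal(nr$narrative, "loss after the divergence of Maxomys")
})

test_that("indeterminate tips can be absorbed into a loss clade", {
  tree <- ape::read.tree(text = "((A,(B,(C,D))),E);")
  st <- status_tbl(tree, pseudo = c("C", "D"), indet = "B")
  ev <- dollo_losses(tree, st)
  expect_equal(nrow(ev), 1)
  # deepest placement takes the indeterminate tip into the clade
  expect_setequal(ev$clade_tips[[1]], c("B", "C", "D"))
  shallow <- dollo_losses(tree, st, tie_break = "shallow")
  expect_setequal(shallow$clade_tips[[1]], c("C", "D"))
})

test_that("separated pseudogenized clades need separate losses", {
  tree <- ape::read.tree(text = "(((A,B),C),((D,E),F));")
  st <- status_tbl(tree, pseudo = c("A", "B", "D", "E"))
  ev <- dollo_losses(tree, st)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$n_pseudogenized == 2))
})

test_that("loss counts equal the exhaustive enumeration on small trees", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      tree <- ape::rtree(n)
      calls <- sample(c("intact", "pseudogenized", "indeterminate"),
                      n, replace = TRUE,
                      prob = c(0.45, 0.35, 0.2))
      st <- tibble::tibble(taxon = tree$tip.label, call = calls)
      ev <- dollo_losses(tree, st)
      oracle <- oracle_dollo_min(
        tree, stats::setNames(calls, tree$tip.label)
      )
      expect_equal(nrow(ev), oracle,
                   info = paste("rep", rep, ape::write.tree(tree)))
    }
  })
})

test_that("adding an indeterminate tip never increases the loss count", {
  withr::with_seed(56, {
    for (rep in 1:10) {
      n <- sample(4:7, 1)
      tree <- ape::rtree(n)
      calls <- sample(c("intact", "pseudogenized"), n, replace = TRUE)
      if (!any(calls == "pseudogenized")) calls[1] <- "pseudogenized"
      st <- tibble::tibble(taxon = tree$tip.label, call = calls)
      base_n <- nrow(dollo_losses(tree, st))
      # graft an indeterminate tip onto a random terminal branch
      tree2 <- ape::bind.tree(
        tree, ape::read.tree(text = "(newtip:1);"),
        where = sample(seq_len(n), 1), position = 0.01
      )
      st2 <- dplyr::bind_rows(
        st, tibble::tibble(taxon = "newtip", call = "indeterminate")
      )
      expect_lte(nrow(dollo_losses(tree2, st2)), base_n)
    }
  })
})

test_that("status and tree label mismatches are rejected", {
  tree <- ape::read.tree(text = "((A,B),C);")
  st <- status_tbl(tree)
  expect_error(dollo_losses(tree, st[-1, ]), "missing status")
  st2 <- dplyr::bind_rows(st, tibble::tibble(taxon = "Z", call = "intact"))
  expect_error(dollo_losses(tree, st2), "unknown tip")
})

test_that("narration of an empty event list says so", {
  tree <- ape::read.tree(text = "((A,B),C);")
  ev <- dollo_losses(tree, status_tbl(tree))
  expect_equal(narrate_losses(ev)$narrative, "no loss events")
})
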