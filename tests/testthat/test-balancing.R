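test_that("r90 is the hand-worked clockwise permutation and has order 4", {
  img <- tile_image(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  r <- dihedral_apply(img, "r90")
  expect_identical(pixels_of(r), matrix(c(3L, 4L, 1L, 2L), 2, 2))  # [[3,1],[4,2]]
  x <- random_tile(6, 9, seed = 2)
  four <- Reduce(function(a, .) dihedral_apply(a, "r90"), 1:4, x)
  expect_identical(pixels_of(four), pixels_of(x))
  mm <- dihedral_apply(dihedral_apply(x, "m"), "m")
  expect_identical(pixels_of(mm), pixels_of(x))
  expect_identical(pixels_of(dihedral_apply(x, "identity")), pixels_of(x))
})

test_that("the 8 transforms form a closed group with inverses", {
  codes <- dihedral_codes()
  x <- random_tile(5, 5, channels = 3, seed = 14)
  imgs <- lapply(codes, function(cd) pixels_of(dihedral_apply(x, cd)))
  names(imgs) <- codes
  # closure: composing any two transforms lands back in the set
  for (a in codes) for (b in codes) {
    comp <- pixels_of(dihedral_apply(dihedral_apply(x, a), b))
    expect_true(any(vapply(imgs, identical, logical(1), comp)),
                info = paste(a, "then", b))
  }
  # every element has an inverse: some c with c(a(x)) = x
  for (a in codes) {
    ax <- dihedral_apply(x, a)
    inv <- any(vapply(codes, function(cd) {
      identical(pixels_of(dihedral_apply(ax, cd)), pixels_of(x))
    }, logical(1)))
    expect_true(inv, info = a)
  }
})

test_that("a generic tile yields exactly 7 pairwise-distinct augmentations", {
  img <- random_tile(3, 3, seed = 19)
  aug <- enumerate_augmentations(img)
  expect_equal(nrow(aug), 7)
  arrays <- lapply(aug$image, pixels_of)
  for (i in 1:6) for (j in (i + 1):7) {
    expect_false(identical(arrays[[i]], arrays[[j]]))
  }
  for (a in arrays) expect_false(identical(a, pixels_of(img)))
})

test_that("symmetric tiles collapse augmentations", {
  const <- tile_image(matrix(9, 4, 4))
  aug <- enumerate_augmentations(const)
  expect_true(all(vapply(aug$image, function(i) {
    identical(pixels_of(i), pixels_of(const))
  }, logical(1))))
  # rows identical (horizontal gradient along columns): r180 == m
  grad <- tile_image(matrix(rep(seq(0, 240, length.out = 4), each = 4), 4, 4))
  ga <- enumerate_augmentations(grad)
  arrays <- lapply(ga$image, pixels_of)
  expect_identical(arrays[[which(ga$transform == "r180")]],
                   arrays[[which(ga$transform == "m")]])
  expect_lt(length(unique(arrays)), 7)
})

test_that("the one-eighth rule passes at the boundary and names offenders", {
  expect_true(check_eighth_rule(c(A = 800, B = 100))$pass)
  chk <- check_eighth_rule(c(A = 900, B = 100))
  expect_false(chk$pass)
  expect_equal(chk$offending, "B")
  expect_true(check_eighth_rule(c(A = 10, B = 10))$pass)
  expect_error(check_eighth_rule(c(A = 5)), class = "histotile_value_error")
  expect_error(check_eighth_rule(c(A = 5, B = 0)),
               class = "histotile_value_error")
})

test_that("to_max plans the deficit without duplicate (source, transform) pairs", {
  root <- make_tree(list(A = list(p1 = 10), B = list(p2 = 4)))
  idx <- scan_dataset(root)
  plan <- plan_balance(idx, "to_max", seed = 5)
  creates <- plan[plan$op == "create", ]
  expect_equal(nrow(creates), 6)
  expect_true(all(creates$class_label == "B"))
  expect_equal(anyDuplicated(paste(creates$path, creates$transform)), 0L)
  expect_lte(max(table(creates$path)), 2)  # 6 <= 2 * 4 sources
  # determinism
  plan2 <- plan_balance(idx, "to_max", seed = 5)
  expect_identical(tibble::as_tibble(plan), tibble::as_tibble(plan2))
})

test_that("planner never duplicates pairs even at deficits up to 7x", {
  # 2 sources in the small class, largest class 16 = 8x2 boundary fails;
  # use counts that pass the rule exactly and exercise every round depth
  for (n_big in c(8, 12, 16)) {
    root <- make_tree(list(A = stats::setNames(list(n_big), "p1"),
                           B = list(p2 = 2)))
    idx <- scan_dataset(root)
    plan <- plan_balance(idx, "to_max", seed = n_big)
    creates <- plan[plan$op == "create", ]
    expect_equal(nrow(creates), n_big - 2)
    expect_equal(anyDuplicated(paste(creates$path, creates$transform)), 0L)
  }
})

test_that("augmentation balancing enforces the one-eighth precondition", {
  root <- make_tree(list(A = list(p1 = 9), B = list(p2 = 1)))
  idx <- scan_dataset(root)
  expect_error(plan_balance(idx, "to_max", seed = 1),
               class = "histotile_precondition_error",
               regexp = "one eighth")
})

test_that("to_mean reduces above-target classes and augments below", {
  root <- make_tree(list(A = list(p1 = 8), B = list(p2 = 4), C = list(p3 = 3)))
  idx <- scan_dataset(root)
  plan <- plan_balance(idx, "to_mean", seed = 2)
  targets <- attr(plan, "targets")
  expect_true(all(targets == 5))
  expect_equal(sum(plan$op == "remove" & plan$class_label == "A"), 3)
  expect_equal(sum(plan$op == "create" & plan$class_label == "B"), 1)
  expect_equal(sum(plan$op == "create" & plan$class_label == "C"), 2)
})

test_that("execute_balance equalises counts on disk and relocates removals", {
  root <- make_tree(list(A = list(p1 = 5), B = list(p2 = 3)))
  idx <- scan_dataset(root)
  rep <- balance_dataset(idx, "to_min", seed = 9)
  expect_true(all(rep$target == 3))
  removed <- list.files(file.path(root, "Removed Images"), recursive = TRUE)
  expect_equal(length(removed), 2)
  expect_true(all(startsWith(removed, "A/p1/")))
  # rescanning shows equal counts (ignore the Removed Images subtree)
  kept <- list.files(root, pattern = "png$", recursive = TRUE)
  kept <- kept[!startsWith(kept, "Removed Images")]
  expect_equal(sum(startsWith(kept, "A/")), 3)
  expect_equal(sum(startsWith(kept, "B/")), 3)
  m <- read_manifest(file.path(root, "histotile_manifest.json"))
  expect_equal(m$seed, 9L)
  expect_equal(nrow(m$actions), 2)
})

test_that("to_max execution creates augmented files and is seed-reproducible", {
  build <- function() {
    root <- make_tree(list(A = list(p1 = 4), B = list(p2 = 2)), value = 30)
    # make sources distinguishable so augmented bytes are informative
    files <- list.files(root, pattern = "png$", recursive = TRUE,
                        full.names = TRUE)
    for (i in seq_along(files)) {
      write_tile(random_tile(8, 8, seed = 50 + i), files[i])
    }
    root
  }
  root1 <- build()
  balance_dataset(scan_dataset(root1), "to_max", seed = 11)
  cc1 <- class_counts(scan_dataset(root1))
  expect_true(all(cc1$n == 4))
  aug_files <- list.files(root1, pattern = "_aug-", recursive = TRUE)
  expect_equal(length(aug_files), 2)
  root2 <- build()
  balance_dataset(scan_dataset(root2), "to_max", seed = 11)
  f1 <- sort(list.files(root1, pattern = "png$", recursive = TRUE))
  f2 <- sort(list.files(root2, pattern = "png$", recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readBin(file.path(root1, f), "raw", 1e5),
                     readBin(file.path(root2, f), "raw", 1e5))
  }
})
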