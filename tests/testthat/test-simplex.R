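# the in-package LP kernel, checked against hand-solved programs and an
# external solver

test_that("simplex solves a classic production LP with correct duals", {
  res <- comfba:::lp_solve(c(3, 5),
                           rbind(c(1, 0), c(0, 2), c(3, 2)),
                           c(4, 12, 18), rep("<=", 3),
                           lb = c(0, 0), ub = c(Inf, Inf))
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, 36)
  expect_equal(unname(res$x), c(2, 6))
  expect_equal(res$duals, c(0, 1.5, 1))
})

test_that("simplex handles equalities, free variables and pure box problems", {
  # max 2x + 3y s.t. x + y = 4, x - y >= -2, x free, y free -> (1, 3)
  res <- comfba:::lp_solve(c(2, 3), rbind(c(1, 1), c(1, -1)), c(4, -2),
                           c("==", ">="), lb = c(-Inf, -Inf), ub = c(Inf, Inf))
  expect_equal(res$objective, 11)
  expect_equal(unname(res$x), c(1, 3))

  res <- comfba:::lp_solve(c(-1), lb = -3, ub = 5)
  expect_equal(res$objective, 3)
  expect_equal(unname(res$x), -3)
})

test_that("simplex certifies infeasibility and unboundedness", {
  res <- comfba:::lp_solve(c(1), rbind(1), 1, ">=", lb = 0, ub = 0.5)
  expect_equal(res$status, "infeasible")

  res <- comfba:::lp_solve(c(1, 0), rbind(c(1, -1)), 0, "<=",
                           lb = c(0, 0), ub = c(Inf, Inf),
                           var_names = c("ray", "other"))
  expect_equal(res$status, "unbounded")
  expect_type(res$unbounded_var, "character")
})

test_that("simplex agrees with an external LP solver on seeded random programs", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  py <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
d = json.load(open(sys.argv[1]))
out = []
for p in d:
    A = np.array(p["A"], float).reshape(p["m"], p["n"])
    obj = np.array(p["obj"], float)
    lb = [x if x is not None else -np.inf for x in p["lb"]]
    ub = [x if x is not None else np.inf for x in p["ub"]]
    Aub, bub, Aeq, beq = [], [], [], []
    for i, s in enumerate(p["dir"]):
        if s == "<=": Aub.append(A[i]); bub.append(p["rhs"][i])
        elif s == ">=": Aub.append(-A[i]); bub.append(-p["rhs"][i])
        else: Aeq.append(A[i]); beq.append(p["rhs"][i])
    r = linprog(-obj, A_ub=np.array(Aub) if Aub else None,
                b_ub=np.array(bub) if bub else None,
                A_eq=np.array(Aeq) if Aeq else None,
                b_eq=np.array(beq) if beq else None,
                bounds=list(zip(lb, ub)), method="highs")
    st = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(r.status, "other")
    out.append({"status": st, "objective": -r.fun if r.status == 0 else None})
print(json.dumps(out))
'
  set.seed(20260927)
  probs <- lapply(1:20, function(i) {
    n <- sample(2:6, 1); m <- sample(1:5, 1)
    lb <- ifelse(runif(n) < .2, -Inf, sample(-2:0, n, TRUE))
    ub <- pmax(ifelse(runif(n) < .3, Inf, sample(1:6, n, TRUE)),
               ifelse(is.finite(lb), lb, -1))
    list(n = jsonlite::unbox(n), m = jsonlite::unbox(m),
         A = as.vector(t(matrix(sample(-3:3, m * n, TRUE), m, n))),
         rhs = sample(-5:8, m, TRUE),
         dir = sample(c("<=", ">=", "=="), m, TRUE, prob = c(.5, .25, .25)),
         obj = sample(-4:4, n, TRUE), lb = lb, ub = ub)
  })
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(probs, inp, digits = NA, null = "null")
  pys <- tempfile(fileext = ".py")
  writeLines(py, pys)
  out <- system2("python", c(pys, inp), stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""),
                            simplifyVector = FALSE)
  for (i in seq_along(probs)) {
    p <- probs[[i]]
    A <- matrix(p$A, p$m, p$n, byrow = TRUE)
    r <- comfba:::lp_solve(p$obj, A, p$rhs, p$dir, lb = p$lb, ub = p$ub)
    expect_equal(r$status, ref[[i]]$status, info = paste("problem", i))
    if (r$status == "optimal")
      expect_equal(r$objective, ref[[i]]$objective, tolerance = 1e-7,
                   info = paste("problem", i))
  }
})
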