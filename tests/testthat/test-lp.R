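# The simplex backend: hand-checkable cases plus a randomized
# cross-check against an independent LP solver.

test_that("simplex solves a flux chain and detects infeasibility", {
  # chain A -> B -> C with uptake 10: conservation forces all fluxes to 10
  Aeq <- rbind(c(1, -1, 0), c(0, 1, -1))
  sol <- beeknock:::solve_lp(c(0, 0, 1), Aeq, c(0, 0), c("=", "="),
                             lb = rep(0, 3), ub = c(10, 1000, 1000),
                             maximize = TRUE)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10)
  expect_equal(sol$x, c(10, 10, 10))

  # x1 + x2 = 5 with both variables capped at 1 is infeasible
  sol2 <- beeknock:::solve_lp(c(1, 1), rbind(c(1, 1)), 5, "=",
                              lb = c(0, 0), ub = c(1, 1))
  expect_equal(sol2$status, "infeasible")

  # degenerate: empty constraint set, minimize over the box
  sol3 <- beeknock:::solve_lp(c(1, -1), lb = c(-2, -3), ub = c(4, 5))
  expect_equal(sol3$objective, -2 - 5)
})

test_that("simplex agrees with scipy on randomized bounded LPs", {
  set.seed(2024)
  cases <- lapply(1:25, function(i) {
    n <- sample(2:8, 1); m <- sample(1:5, 1)
    A <- matrix(round(rnorm(m * n), 2), m, n)
    sense <- sample(c("=", "<=", ">="), m, replace = TRUE)
    lb <- round(runif(n, -10, 0), 2); ub <- round(runif(n, 0, 10), 2)
    x0 <- runif(n, lb, ub)
    slack <- ifelse(sense == "<=", abs(rnorm(m)),
                    ifelse(sense == ">=", -abs(rnorm(m)), 0))
    b <- round(as.vector(A %*% x0) + slack, 3)
    # half the cases get a perturbed rhs that may be infeasible
    if (i %% 2 == 0) b <- b + round(rnorm(m, sd = 4), 2)
    list(obj = round(rnorm(n), 2), A = A, b = b, sense = sense,
         lb = lb, ub = ub)
  })
  ours <- lapply(cases, function(p)
    beeknock:::solve_lp(p$obj, p$A, p$b, p$sense, p$lb, p$ub))

  payload <- lapply(cases, function(p)
    list(obj = p$obj, A = as.vector(t(p$A)), m = nrow(p$A),
         n = length(p$obj), b = p$b, sense = as.list(p$sense),
         lb = p$lb, ub = p$ub))
  ref <- py_oracle('
import numpy as np
from scipy.optimize import linprog
cases = json.load(open(IN_FILE))
out = []
for c in cases:
    m, n = c["m"], c["n"]
    A = np.atleast_1d(np.array(c["A"], float)).reshape(m, n)
    b = np.atleast_1d(np.array(c["b"], float))
    obj = np.atleast_1d(np.array(c["obj"], float))
    lb = np.atleast_1d(np.array(c["lb"], float))
    ub = np.atleast_1d(np.array(c["ub"], float))
    Aeq, beq, Aub, bub = [], [], [], []
    for i, s in enumerate(c["sense"]):
        if s == "=": Aeq.append(A[i]); beq.append(b[i])
        elif s == "<=": Aub.append(A[i]); bub.append(b[i])
        else: Aub.append(-A[i]); bub.append(-b[i])
    r = linprog(obj, A_ub=np.array(Aub) if Aub else None, b_ub=bub or None,
                A_eq=np.array(Aeq) if Aeq else None, b_eq=beq or None,
                bounds=list(zip(lb, ub)), method="highs")
    st = "optimal" if r.status == 0 else ("infeasible" if r.status == 2 else "other")
    out.append({"status": st, "objective": r.fun if r.status == 0 else None})
json.dump(out, open(OUT_FILE, "w"))
', payload)

  for (i in seq_along(cases)) {
    expect_equal(ours[[i]]$status, ref$status[i],
                 label = paste("status of case", i))
    if (ref$status[i] == "optimal") {
      expect_equal(ours[[i]]$objective, ref$objective[i], tolerance = 1e-6,
                   label = paste("objective of case", i))
    }
  }
})
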