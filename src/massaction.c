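/* Generic mass-action right-hand side for deSolve.
 *
 * The active network is installed from R via C_ma_set_network() before
 * integration; C_ma_deriv() is then resolved by deSolve through the package
 * DLL. Reactions have at most two reactants; the stoichiometry is stored
 * sparse in CSC-by-reaction layout.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <stdlib.h>

static int nsp = 0, nrx = 0, nnz = 0;
static double *kv = NULL;     /* rate constants, length nrx */
static int *r1 = NULL;        /* first reactant, 1-based, length nrx */
static int *r2 = NULL;        /* second reactant, 1-based, 0 = none */
static int *ptr = NULL;       /* CSC pointers, length nrx + 1 (0-based) */
static int *spi = NULL;       /* species index per nonzero, 1-based */
static double *sto = NULL;    /* stoichiometric coefficient per nonzero */

static void ma_free(void)
{
    free(kv); free(r1); free(r2); free(ptr); free(spi); free(sto);
    kv = NULL; r1 = NULL; r2 = NULL; ptr = NULL; spi = NULL; sto = NULL;
    nsp = nrx = nnz = 0;
}

SEXP C_ma_set_network(SEXP Rnsp, SEXP Rk, SEXP Rr1, SEXP Rr2,
                      SEXP Rptr, SEXP Rspi, SEXP Rsto)
{
    ma_free();
    nsp = INTEGER(Rnsp)[0];
    nrx = LENGTH(Rk);
    nnz = LENGTH(Rspi);
    kv = (double *) malloc(sizeof(double) * (nrx > 0 ? nrx : 1));
    r1 = (int *) malloc(sizeof(int) * (nrx > 0 ? nrx : 1));
    r2 = (int *) malloc(sizeof(int) * (nrx > 0 ? nrx : 1));
    ptr = (int *) malloc(sizeof(int) * (nrx + 1));
    spi = (int *) malloc(sizeof(int) * (nnz > 0 ? nnz : 1));
    sto = (double *) malloc(sizeof(double) * (nnz > 0 ? nnz : 1));
    if (!kv || !r1 || !r2 || !ptr || !spi || !sto) {
        ma_free();
        error("mitoapop: allocation failure in C_ma_set_network");
    }
    for (int j = 0; j < nrx; j++) {
        kv[j] = REAL(Rk)[j];
        r1[j] = INTEGER(Rr1)[j];
        r2[j] = INTEGER(Rr2)[j];
    }
    for (int j = 0; j <= nrx; j++) ptr[j] = INTEGER(Rptr)[j];
    for (int p = 0; p < nnz; p++) {
        spi[p] = INTEGER(Rspi)[p];
        sto[p] = REAL(Rsto)[p];
    }
    return ScalarInteger(nrx);
}

void C_ma_init(void (*odeparms)(int *, double *))
{
    int n = 0;
    double dummy = 0.0;
    odeparms(&n, &dummy);
}

void C_ma_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    for (int i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (int j = 0; j < nrx; j++) {
        double rate = kv[j];
        if (r1[j] > 0) rate *= y[r1[j] - 1];
        if (r2[j] > 0) rate *= y[r2[j] - 1];
        for (int p = ptr[j]; p < ptr[j + 1]; p++)
            ydot[spi[p] - 1] += sto[p] * rate;
    }
}

static const R_CallMethodDef callMethods[] = {
    {"C_ma_set_network", (DL_FUNC) &C_ma_set_network, 7},
    {NULL, NULL, 0}
};

void R_init_mitoapop(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
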