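/* Compiled right-hand side and Jacobian of the 7D mean-field system for
 * deSolve's compiled-model interface. Parameter layout must match
 * .flat_params() in R/params.R:
 *  0 tau  1 Vex  2 Vin  3 Ie  4 Ii  5 De  6 Di
 *  7 gee  8 gen  9 gei 10 gie 11 gin 12 gii
 * 13 cee 14 cen 15 cei 16 cie 17 cin 18 cii
 * 19 taue 20 taui 21 taun 22 an
 * State: 0 re, 1 ue, 2 se, 3 ri, 4 ui, 5 si, 6 sn.
 */
#include <R.h>
#include <math.h>

static double parms[23];

#define TAU  parms[0]
#define VEX  parms[1]
#define VIN  parms[2]
#define IE   parms[3]
#define II   parms[4]
#define DE   parms[5]
#define DI   parms[6]
#define GEE  parms[7]
#define GEN  parms[8]
#define GEI  parms[9]
#define GIE  parms[10]
#define GIN  parms[11]
#define GII  parms[12]
#define CEE  parms[13]
#define CEN  parms[14]
#define CEI  parms[15]
#define CIE  parms[16]
#define CIN  parms[17]
#define CII  parms[18]
#define TAUE parms[19]
#define TAUI parms[20]
#define TAUN parms[21]
#define AN   parms[22]

static double sgn(double x) { return (x > 0) - (x < 0); }

void mf_initmod(void (*odeparms)(int *, double *)) {
  int n = 23;
  odeparms(&n, parms);
}

void mf_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
               int *ip) {
  const double re = y[0], ue = y[1], se = y[2], ri = y[3], ui = y[4],
               si = y[5], sn = y[6];
  const double aExE = fabs(ue - VEX), aInE = fabs(ue - VIN);
  const double aExI = fabs(ui - VEX), aInI = fabs(ui - VIN);
  const double sExE = sgn(VEX - ue), sInE = sgn(VIN - ue);
  const double sExI = sgn(VEX - ui), sInI = sgn(VIN - ui);
  const double Ae = GEE * se + GEI * si + GEN * sn;
  const double Ai = GIE * se + GII * si + GIN * sn;
  const double He = DE + CEE * se * aExE + CEI * si * aInE + CEN * sn * aExE;
  const double Hi = DI + CIE * se * aExI + CII * si * aInI + CIN * sn * aExI;
  const double Ge = (CEE * se + CEN * sn) * sExE + CEI * si * sInE;
  const double Gi = (CIE * se + CIN * sn) * sExI + CII * si * sInI;
  const double tpt2 = 2.0 * M_PI * TAU * TAU;

  ydot[0] = (re * ue - Ae * re) / TAU + He / tpt2;
  ydot[1] = (0.5 * (ue * ue - 1.0) + IE - GEE * se * (ue - VEX) -
             GEI * si * (ue - VIN) - GEN * sn * (ue - VEX)) / TAU -
            2.0 * M_PI * M_PI * TAU * re * re + 2.0 * M_PI * re * Ge;
  ydot[2] = -se / TAUE + re;
  ydot[3] = (ri * ui - Ai * ri) / TAU + Hi / tpt2;
  ydot[4] = (0.5 * (ui * ui - 1.0) + II - GIE * se * (ui - VEX) -
             GII * si * (ui - VIN) - GIN * sn * (ui - VEX)) / TAU -
            2.0 * M_PI * M_PI * TAU * ri * ri + 2.0 * M_PI * ri * Gi;
  ydot[5] = -si / TAUI + ri;
  ydot[6] = AN * se * (1.0 - sn) - sn / TAUN;
}

/* Full Jacobian, column-major in pd (nrowpd x neq). */
void mf_jac(int *neq, double *t, double *y, int *ml, int *mu, double *pd,
            int *nrowpd, double *yout, int *ip) {
  const double re = y[0], ue = y[1], se = y[2], ri = y[3], ui = y[4],
               si = y[5], sn = y[6];
  const int n = *nrowpd;
  const double aExE = fabs(ue - VEX), aInE = fabs(ue - VIN);
  const double aExI = fabs(ui - VEX), aInI = fabs(ui - VIN);
  const double sExE = sgn(VEX - ue), sInE = sgn(VIN - ue);
  const double sExI = sgn(VEX - ui), sInI = sgn(VIN - ui);
  const double Ae = GEE * se + GEI * si + GEN * sn;
  const double Ai = GIE * se + GII * si + GIN * sn;
  const double Ge = (CEE * se + CEN * sn) * sExE + CEI * si * sInE;
  const double Gi = (CIE * se + CIN * sn) * sExI + CII * si * sInI;
  const double tpt2 = 2.0 * M_PI * TAU * TAU;
  int i, j;
  for (j = 0; j < 7; j++)
    for (i = 0; i < 7; i++) pd[i + n * j] = 0.0;

#define PD(i, j) pd[(i) + n * (j)]
  PD(0, 0) = (ue - Ae) / TAU;
  PD(0, 1) = re / TAU + (CEE * se * sgn(ue - VEX) + CEI * si * sgn(ue - VIN) +
                         CEN * sn * sgn(ue - VEX)) / tpt2;
  PD(0, 2) = -GEE * re / TAU + CEE * aExE / tpt2;
  PD(0, 5) = -GEI * re / TAU + CEI * aInE / tpt2;
  PD(0, 6) = -GEN * re / TAU + CEN * aExE / tpt2;

  PD(1, 0) = -4.0 * M_PI * M_PI * TAU * re + 2.0 * M_PI * Ge;
  PD(1, 1) = (ue - GEE * se - GEI * si - GEN * sn) / TAU;
  PD(1, 2) = -GEE * (ue - VEX) / TAU + 2.0 * M_PI * re * CEE * sExE;
  PD(1, 5) = -GEI * (ue - VIN) / TAU + 2.0 * M_PI * re * CEI * sInE;
  PD(1, 6) = -GEN * (ue - VEX) / TAU + 2.0 * M_PI * re * CEN * sExE;

  PD(2, 0) = 1.0;
  PD(2, 2) = -1.0 / TAUE;

  PD(3, 3) = (ui - Ai) / TAU;
  PD(3, 4) = ri / TAU + (CIE * se * sgn(ui - VEX) + CII * si * sgn(ui - VIN) +
                         CIN * sn * sgn(ui - VEX)) / tpt2;
  PD(3, 2) = -GIE * ri / TAU + CIE * aExI / tpt2;
  PD(3, 5) = -GII * ri / TAU + CII * aInI / tpt2;
  PD(3, 6) = -GIN * ri / TAU + CIN * aExI / tpt2;

  PD(4, 3) = -4.0 * M_PI * M_PI * TAU * ri + 2.0 * M_PI * Gi;
  PD(4, 4) = (ui - GIE * se - GII * si - GIN * sn) / TAU;
  PD(4, 2) = -GIE * (ui - VEX) / TAU + 2.0 * M_PI * ri * CIE * sExI;
  PD(4, 5) = -GII * (ui - VIN) / TAU + 2.0 * M_PI * ri * CII * sInI;
  PD(4, 6) = -GIN * (ui - VEX) / TAU + 2.0 * M_PI * ri * CIN * sExI;

  PD(5, 3) = 1.0;
  PD(5, 5) = -1.0 / TAUI;

  PD(6, 2) = AN * (1.0 - sn);
  PD(6, 6) = -AN * se - 1.0 / TAUN;
#undef PD
}
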