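static void vwn5_cpot(double ra, double rb, double* ec, double* va, double* vb) {
  double x0 = ra + rb;
  double x1 = pow(2, 2.0/3.0);
  double x2 = pow(3, 1.0/6.0);
  double x3 = pow(M_PI, -1.0/6.0);
  double x4 = x1*x2*x3;
  double x5 = x4/pow(x0, 1.0/6.0);
  double x6 = x5 + 3.7274400000000001;
  double x7 = atan(6.1519908197590798/x6);
  double x8 = cbrt(6)/cbrt(M_PI);
  double x9 = x8/cbrt(x0);
  double x10 = 1.0/(3.7274400000000001*x5 + x9 + 25.8704);
  double x11 = log(x10*x9);
  double x12 = x5 + 0.20996000000000001;
  double x13 = log((1.0/2.0)*x10*pow(x12, 2));
  double x14 = x5 + 1.13107;
  double x15 = 1.0/(1.13107*x5 + x9 + 26.009);
  double x16 = x5 + 0.0095168000000000006;
  double x17 = 6.9917323506031452e-6*log((1.0/2.0)*x15*pow(x16, 2)) + 0.01688686394*log(x15*x9) + 0.005365091848759814*atan(7.1231089178181177/x14);
  double x18 = pow(x0, -4);
  double x19 = ra - rb;
  double x20 = pow(x19, 4);
  double x21 = x18*x20;
  double x22 = x21 - 1;
  double x23 = 1.0/x0;
  double x24 = x19*x23;
  double x25 = x24 + 1;
  double x26 = pow(x25, 4.0/3.0);
  double x27 = x24 - 1;
  double x28 = -x27;
  double x29 = x26 + pow(x28, 4.0/3.0) - 2;
  double x30 = x22*x29;
  double x31 = x17*x30;
  double x32 = 1.0/(1 - cbrt(2));
  double x33 = x5 + 7.0604199999999997;
  double x34 = 1.0/(7.0604199999999997*x5 + x9 + 36.115600000000001);
  double x35 = x5 + 0.65000000000000002;
  double x36 = x32*(0.031090699999999999*x11 + 0.00096902277115443745*x13 + 0.038783294878113016*x7 - 0.0022478670955426118*log((1.0/2.0)*x34*pow(x35, 2)) - 0.015545349999999999*log(x34*x9) - 0.052491393169780923*atan(4.7309269095601136/x33));
  double x37 = x29*x36;
  double x38 = x21*x37;
  double x39 = x18*pow(x19, 3);
  double x40 = 108*x17*x29*x39;
  double x41 = 36*x17*x22*x23;
  double x42 = cbrt(x28);
  double x43 = x27*(-cbrt(x25) + x42);
  double x44 = 48*x37;
  double x45 = x39*x44;
  double x46 = x20/pow(x0, 5);
  double x47 = 16*x36*x46;
  double x48 = 1.0/x12;
  double x49 = pow(x0, -7.0/6.0);
  double x50 = x4*x49;
  double x51 = x8/pow(x0, 4.0/3.0);
  double x52 = 1.86372*x50 + x51;
  double x53 = x10*x52;
  double x54 = 0.00032300759038481248*x12*x53 - 0.00032300759038481248*x50;
  double x55 = pow(x14, -2);
  double x56 = x15*(0.56553500000000001*x50 + x51);
  double x57 = pow(x6, -2);
  double x58 = 1.0/(37.846991046399992*x57 + 1);
  double x59 = pow(x33, -2);
  double x60 = x34*(3.5302099999999994*x50 + x51);
  double x61 = 12*x21*x29*x32*(0.039765745675026769*x1*x2*x3*x49*x57*x58 + 0.010363566666666666*x10*x52 - 0.0051817833333333329*x23 + x48*x54 - 0.041388824077869417*x50*x59/(22.381669423600009*x59 + 1) - 0.0051817833333333329*x60 - (0.00074928903184753718*x35*x60 - 0.00074928903184753718*x50)/x35) - 0.24872559999999999*x23 + 27*x30*(-0.0056289546466666666*x23 + 0.0063693555988023863*x50*x55/(50.738680655099998*x55 + 1) + 0.0056289546466666666*x56 + (2.3305774502010483e-6*x16*x56 - 2.3305774502010483e-6*x50)/x16) - x44*x46 + 24*x48*x54 + 0.95437789620064228*x50*x57*x58 + 0.24872559999999999*x53;
  double x62 = 0.74617679999999997*x11 + 0.023256546507706498*x13 + 27*x31 + 12*x38 + 0.93079907707471232*x7;
  double x63 = x25*x42 - x26;
  *ec = (1.0/8.0)*x0*(0.24872559999999999*x11 + 0.0077521821692354996*x13 + 9*x31 + 4*x38 + 0.31026635902490413*x7);
  *va = (1.0/24.0)*x0*(-x27*x40 + x41*x43 + x43*x47 + x45 + x61) + (1.0/24.0)*x62;
  *vb = (1.0/24.0)*x0*(-x25*x40 + x41*x63 - x45 + x47*x63 + x61) + (1.0/24.0)*x62;
}

static void pbec_cpot(double ra, double rb, double g, double* ec, double* va, double* vb, double* vg) {
  double x0 = ra + rb;
  double x1 = cbrt(6);
  double x2 = cbrt(M_PI);
  double x3 = 1.0/x2;
  double x4 = x1*x3;
  double x5 = x4/cbrt(x0);
  double x6 = 0.0066441466999999999*x5 + 0.062182000000000001;
  double x7 = sqrt(3)/sqrt(M_PI);
  double x8 = x7/sqrt(x0);
  double x9 = pow(6, 2.0/3.0)/pow(M_PI, 2.0/3.0);
  double x10 = x9/pow(x0, 2.0/3.0);
  double x11 = pow(2, 2.0/3.0)*pow(3, 1.0/6.0)/pow(M_PI, 1.0/6.0);
  double x12 = x11/pow(x0, 1.0/6.0);
  double x13 = 0.0076629987700000003*x10 + 0.2361579087*x12 + 0.1115420716*x5 + 0.050933276200000002*x8;
  double x14 = 1 + 1.0/x13;
  double x15 = log(x14);
  double x16 = x15*x6;
  double x17 = ra - rb;
  double x18 = 1.0/x0;
  double x19 = x17*x18;
  double x20 = x19 + 1;
  double x21 = pow(x20, 4.0/3.0);
  double x22 = x19 - 1;
  double x23 = -x22;
  double x24 = x21 + pow(x23, 4.0/3.0) - 2;
  double x25 = (9.0/8.0)*x24;
  double x26 = pow(x0, -4);
  double x27 = pow(x17, 4);
  double x28 = x26*x27;
  double x29 = x28 - 1;
  double x30 = 0.00187867875*x5 + 0.033773999999999998;
  double x31 = 0.0041939708849999995*x10 + 0.17489865899999998*x12 + 0.061183289699999997*x5 + 0.014864950619999999*x8;
  double x32 = 1 + 1.0/x31;
  double x33 = log(x32);
  double x34 = x30*x33;
  double x35 = x29*x34;
  double x36 = x25*x35;
  double x37 = x24*x28;
  double x38 = (1.0/2.0)*x37;
  double x39 = 1 - cbrt(2);
  double x40 = 1.0/x39;
  double x41 = 0.0031941866000000001*x5 + 0.03109;
  double x42 = 0.0048591338249999996*x10 + 0.2194783005*x12 + 0.096343246500000007*x5 + 0.052327578999999999*x8;
  double x43 = 1 + 1.0/x42;
  double x44 = log(x43);
  double x45 = -x16;
  double x46 = x41*x44 + x45;
  double x47 = x40*x46;
  double x48 = x38*x47;
  double x49 = 1 - M_LN2;
  double x50 = pow(x49, -2);
  double x51 = -x29;
  double x52 = x34*x51;
  double x53 = -1/x39;
  double x54 = -x46;
  double x55 = x53*x54;
  double x56 = x25*x52 + x38*x55 + x45;
  double x57 = pow(M_PI, 2);
  double x58 = 1.0/x49;
  double x59 = pow(x20, 2.0/3.0);
  double x60 = pow(x23, 2.0/3.0) + x59;
  double x61 = pow(x60, 3);
  double x62 = x58/x61;
  double x63 = x57*x62;
  double x64 = 8*x63;
  double x65 = exp(-x56*x64);
  double x66 = 1 - x65;
  double x67 = -x66;
  double x68 = x50/pow(x67, 2);
  double x69 = cbrt(3);
  double x70 = 9.275345110817127e-5*x69;
  double x71 = pow(M_PI, 14.0/3.0)*pow(g, 2)*x70/(pow(x0, 14.0/3.0)*pow(x60, 4));
  double x72 = pow(3, 2.0/3.0);
  double x73 = 0.0055603792169291017*x72;
  double x74 = 1.0/x67;
  double x75 = pow(x0, -7.0/3.0);
  double x76 = pow(M_PI, 7.0/3.0);
  double x77 = pow(x60, 2);
  double x78 = x58*x76/x77;
  double x79 = g*x78;
  double x80 = x75*x79;
  double x81 = x74*x80;
  double x82 = x73*x81 + 1;
  double x83 = 1.0/(x68*x71 + x82);
  double x84 = x72*x82;
  double x85 = x49/x57;
  double x86 = (1.0/8.0)*x61*x85;
  double x87 = 48*x24;
  double x88 = x47*x87;
  double x89 = pow(x17, 3)*x26;
  double x90 = x88*x89;
  double x91 = 108*x24*x34*x89;
  double x92 = x22*x91;
  double x93 = pow(x0, -5);
  double x94 = cbrt(x23);
  double x95 = cbrt(x20);
  double x96 = x94 - x95;
  double x97 = 36*x18;
  double x98 = x35*x97;
  double x99 = 0.012974218172834571*x84;
  double x100 = 1.0/x94;
  double x101 = x100*x22;
  double x102 = 1.0/x95;
  double x103 = x102*x23;
  double x104 = x101 + x103;
  double x105 = 1.0/x60;
  double x106 = 0.0074138389559054689*x105*x84;
  double x107 = 0.012974218172834571*x18;
  double x108 = x105*x18;
  double x109 = -8*x15*x6 + 9*x24*x52 + 4*x37*x55;
  double x110 = -x109;
  double x111 = x104*x108;
  double x112 = x22*x94 + x23*x95;
  double x113 = x27*x93;
  double x114 = 16*x113;
  double x115 = x114*x55;
  double x116 = x52*x97;
  double x117 = x55*x87*x89;
  double x118 = x7/pow(x0, 3.0/2.0);
  double x119 = pow(x0, -4.0/3.0);
  double x120 = x119*x4;
  double x121 = x9/pow(x0, 5.0/3.0);
  double x122 = x11/pow(x0, 7.0/6.0);
  double x123 = x6*(0.025466638100000001*x118 + 0.037180690533333331*x120 + 0.0051086658466666665*x121 + 0.039359651449999998*x122)/(pow(x13, 2)*x14);
  double x124 = 24*x123;
  double x125 = x120*x15;
  double x126 = 0.053153173599999999*x125;
  double x127 = -0.0010647288666666666*x120*x44 - x123 + 0.0022147155666666666*x125 + x41*(0.0261637895*x118 + 0.0321144155*x120 + 0.0032394225499999996*x121 + 0.036579716749999998*x122)/(pow(x42, 2)*x43);
  double x128 = 12*x37;
  double x129 = 27*x30*(0.0074324753099999996*x118 + 0.020394429899999997*x120 + 0.0027959805899999994*x121 + 0.029149776499999995*x122)/(pow(x31, 2)*x32);
  double x130 = -0.016908108750000001*x1*x119*x24*x3*x33*x51 - x124 + x126 - x127*x128*x53 + x129*x24*x51 - 48*x24*x27*x53*x54*x93;
  double x131 = x112*x115 + x112*x116 + x117 + x130 + x92;
  double x132 = exp(-x56*x64);
  double x133 = 1.0/(x132 - 1);
  double x134 = 0.0018534597389763672*x132*x133*x63;
  double x135 = x119*x79;
  double x136 = 0.016681137650787305*x133*x135*x69;
  double x137 = 0.17793213494173125*x69;
  double x138 = x65*(6*x104*x105*x109*x18 - x131);
  double x139 = 0.044483033735432813*x63*x69*x74;
  double x140 = g/pow(x0, 10.0/3.0);
  double x141 = x140*x74;
  double x142 = 0.0059362208709229613*x141*x62*x76;
  double x143 = 0.0014840552177307403*pow(M_PI, 13.0/3.0)*g*x68*x75/pow(x60, 5);
  double x144 = 0.010388386524115182*x141*x78 + 0.31138123614802969*x18*x69;
  double x145 = 0.00069504740211613771*x135*x74*x82*x83;
  double x146 = x80/x66;
  double x147 = x146*x73;
  double x148 = 1.0/(-x147 + x50*x71/pow(x66, 2) + 1);
  double x149 = 1 - x147;
  double x150 = x148*x149*x73*x80 + 1;
  double x151 = x2*x60/x150;
  double x152 = 3*x140*x151*x83;
  double x153 = log(x150);
  double x154 = 6*x153*x18*x77*x85;
  double x155 = x24*x29;
  double x156 = x113*x88 - 0.016908108750000001*x120*x155*x33 + x124 - x126 - x127*x128*x40 + x129*x155;
  double x157 = (1.0/24.0)*x0;
  double x158 = x153*x86 - x36 + x45 + x48;
  double x159 = x100*x20;
  double x160 = -x159 + x59;
  double x161 = -x160;
  double x162 = x20*x94 - x21;
  double x163 = x20*x91;
  double x164 = -x114*x162*x47 + x156 + x162*x98 - x163 + x90;
  double x165 = x65*(6*x108*x109*x161 + x164);
  *ec = -x0*(x16 + x36 - x48 - x86*log(0.0055603792169291017*x80*x83*x84 + 1));
  *va = x157*(-x152*(x104*x106 + x136*(x107 + x108*(0.0074138389559054689*x101 + 0.0074138389559054689*x103) + x134*(-6*x110*x111 - x131)) - x145*(x104*x142 + x111*x137 + x138*x139 + x138*x143 + x144) + x99) - x154*x22*(-x100 + x102) - x156 + 16*x22*x27*x40*x46*x93*x96 - x22*x96*x98 + x90 + x92) + x158;
  *vb = x157*(-x152*(x106*x161 + x136*(x107 - x108*(-0.0074138389559054689*x159 + 0.0074138389559054689*x59) + x134*(6*x105*x110*x160*x18 - x115*x162 - x116*x162 + x117 - x130 - x163)) - x145*(x108*x137*x161 + x139*x165 + x142*x161 + x143*x165 + x144) + x99) - x154*x160 - x164) + x158;
  *vg = (1.0/8.0)*x119*x148*x151*(-x146*x70 - 0.016681137650787305*x148*x149*x81*(0.0055603792169291017*x69 + 0.00018550690221634254*x81) + 0.0055603792169291017*x149*x72);
}
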