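u8 <- function(x) pmin(255, pmax(0, floor(abs(x) + 0.5) * sign(x)))
srgb2lab <- function(r, g, b) {  # r,g,b in 0..255
  lin <- function(u) { u <- u/255; ifelse(u <= 0.04045, u/12.92, ((u+0.055)/1.055)^2.4) }
  R <- lin(r); G <- lin(g); B <- lin(b)
  X <- 0.412456439089692*R + 0.357576077643909*G + 0.180437483266399*B
  Y <- 0.212672851405623*R + 0.715152155287818*G + 0.0721749699584796*B
  Z <- 0.0193338955823293*R + 0.119192025881303*G + 0.950304078536368*B
  f <- function(t) ifelse(t > (6/29)^3, t^(1/3), t/(3*(6/29)^2) + 4/29)
  fx <- f(X/0.95047); fy <- f(Y/1); fz <- f(Z/1.08883)
  list(L = 116*fy - 16, a = 500*(fx - fy), b = 200*(fy - fz))
}
intensity <- function(t2, adc, dwi) {
  lab <- srgb2lab(255 - t2, 255 - adc, dwi)
  lum8 <- u8(2.55 * lab$L); comb <- u8(sqrt(lab$a^2 + lab$b^2))
  pmax(0, lum8 - comb)
}
show <- function(name, t2, adc, dwi) cat(sprintf("%-14s t2=%3d adc=%3d dwi=%3d -> I=%d\n", name, t2, adc, dwi, intensity(t2,adc,dwi)))
show("PZ bg",      200,170, 60)
show("TZ bg",      130,150, 70)
show("outside",     40,100, 30)
show("pr5 a",       50, 40,230)
show("pr5 b",       60, 50,220)
show("pr4 a",       80, 70,190)
show("pr4 b",       90, 80,180)
show("pr3tz a",     80,150, 70)
show("pr3tz b",     70,150, 70)
show("shine",      200,220,220)
show("prostatitis",120,170,140)
show("extrapros",   60, 50,220)
cat("\nDWI ladder t2=50 adc=40: ", sapply(c(150,170,190,210,230), function(d) intensity(50,40,d)), "\n")
cat("ADC ladder t2=50 dwi=230: ", sapply(c(120,100,80,60,40), function(a) intensity(50,a,230)), "\n")
cat("T2 ladder adc=40 dwi=230: ", sapply(c(130,110,90,70,50), function(t) intensity(t,40,230)), "\n")
cat("\n-- final candidates --\n")
show("outside2",    40,130, 20)
show("pr5 final",   60, 50,210)
show("pr4 final",   90, 80,180)
show("shine hiDWIloADC", 200, 60, 220)
cat("DWI ladder (60,50,*): ", sapply(seq(130,210,20), function(d) intensity(60,50,d)), "\n")
cat("ADC ladder (60,*,210): ", sapply(seq(130,50,-20), function(a) intensity(60,a,210)), "\n")
cat("T2  ladder (*,50,210): ", sapply(seq(140,60,-20), function(t) intensity(t,50,210)), "\n")
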