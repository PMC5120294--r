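It is interesting to contemplate an entangled bank, clothed with many plants
of many kinds, with birds singing on the bushes, with various insects flitting
about, and with worms crawling through the damp earth, and to reflect that
these elaborately constructed forms, so different from each other, and
dependent on each other in so complex a manner, have all been produced by laws
acting around us. These laws, taken in the largest sense, being Growth with
Reproduction; Inheritance which is almost implied by reproduction; Variability
from the indirect and direct action of the external conditions of life, and
from use and disuse; a Ratio of Increase so high as to lead to a Struggle for
Life, and as a consequence to Natural Selection, entailing Divergence of
Character and the Extinction of less-improved forms. Thus, from the war of
nature, from famine and death, the most exalted object which we are capable of
conceiving, namely, the production of the higher animals, directly follows.
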