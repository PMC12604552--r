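# Default school-procurement range policy, version nutriscore-2023-school.
#
# Rules are evaluated in order; the first rule whose predicate matches the
# product AND whose letters contain the product's letter decides the verdict.
# If no rule fires, the default applies: letters in `default.acceptable` are
# acceptable, everything else is avoid. Predicates: food_group (exact label),
# role (product role metadata, e.g. "bread topping"), max_portion_ml
# (portion size must be known and <= this many ml).
#
# The whole-grain preference ("opt for whole grain instead of refined
# products of flour, rice and pasta") is not expressible as a letter range;
# it is emitted as an advisory annotation for refined products in the listed
# food groups, never as a verdict change.
version: nutriscore-2023-school
default:
  acceptable: [A, B]
advisory:
  whole_grain_groups: [Grains, Bread, Pasta and rice]
rules:
  - id: bread-topping-C
    letters: [C]
    role: bread topping
    verdict: acceptable
    rationale: letter C acceptable for bread toppings
  - id: juice-portion-C
    letters: [C]
    food_group: Beverages
    role: juice
    max_portion_ml: 250
    verdict: acceptable
    rationale: letter C acceptable for juice in portions of at most 250 ml
  - id: fish-topping-D
    letters: [D]
    role: fish-based bread topping
    verdict: acceptable
    rationale: letter D acceptable for fish-based bread toppings
  - id: small-quantity-D
    letters: [D]
    role: small-quantity ingredient
    verdict: acceptable
    rationale: >
      letter D acceptable for ingredients used in small quantities
      (dressings, reduced-fat cream, mayonnaise)
  - id: oil-dressing-E
    letters: [E]
    role: oil-based salad dressing
    verdict: acceptable
    rationale: the single letter-E exception, oil-based salad dressings
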