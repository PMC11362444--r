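a
able
about
above
across
act
add
afraid
after
afternoon
again
against
age
ago
agree
air
all
almost
alone
along
already
also
always
am
among
an
and
angry
animal
another
answer
any
anybody
anyone
anything
apart
are
arm
around
as
ask
asleep
at
ate
away
baby
back
bad
bag
ball
band
bank
base
basket
be
bean
bear
beat
beautiful
became
because
become
bed
been
before
began
begin
behind
being
believe
bell
belong
below
belt
bend
bent
beside
best
better
between
big
bill
bird
birthday
bit
black
blanket
block
blood
blow
blue
board
boat
body
bone
book
born
borrow
both
bottle
bottom
bought
box
boy
brain
branch
brave
bread
break
breakfast
breath
bridge
bright
bring
broke
brother
brought
brown
build
building
built
burn
bus
busy
but
buy
by
cake
call
came
can
cannot
cap
car
card
care
careful
carry
case
cat
catch
caught
cause
cent
center
certain
chair
chance
change
chase
cheap
check
cheer
chicken
chief
child
children
choose
church
circle
city
class
clean
clear
climb
clock
close
cloth
clothes
cloud
coat
cold
collect
color
come
comfort
coming
company
cook
cool
corn
corner
cost
cotton
could
count
country
course
cover
cow
crack
cream
cross
crowd
cry
cup
cut
dad
daily
dance
dark
date
daughter
day
days
dead
deal
dear
decide
deep
desk
did
die
different
dig
dinner
dirty
dish
do
doctor
does
dog
dollar
done
door
double
down
draw
dream
dress
drink
drive
drop
dry
duck
during
dust
each
ear
early
earn
earth
east
easy
eat
edge
egg
eight
either
eleven
else
empty
end
enjoy
enough
even
evening
ever
every
everybody
everyone
everything
exact
except
excuse
expect
explain
eye
face
fact
fair
fall
family
famous
far
farm
fast
fat
father
fault
favor
fear
feed
feel
feeling
feet
fell
felt
fence
few
field
fight
fill
find
fine
finger
finish
fire
first
fish
fit
five
fix
flag
flat
floor
flower
fly
follow
food
foot
for
forget
forgot
form
found
four
free
fresh
friend
friendly
from
front
fruit
full
fun
funny
future
game
garden
gate
gave
general
gentle
get
gift
girl
give
glad
glass
go
goes
gold
gone
good
got
grand
grass
gray
great
green
grew
ground
group
grow
guess
had
hair
half
hall
hand
handle
hang
happen
happy
hard
has
hat
have
he
head
health
hear
heard
heart
heat
heavy
held
hello
help
her
here
herself
hid
hide
high
hill
him
himself
his
hit
hold
hole
holiday
home
honest
hope
horse
hot
hour
house
how
hundred
hungry
hunt
hurry
hurt
husband
i
ice
idea
if
ill
important
in
inch
indeed
inside
instead
into
iron
is
it
its
itself
job
join
joke
joy
jump
just
keep
kept
key
kick
kill
kind
king
kiss
kitchen
knee
knew
knock
know
known
lady
laid
lake
land
large
last
late
laugh
lay
lazy
lead
leaf
learn
least
leave
left
leg
lend
less
let
letter
level
lie
life
lift
light
like
line
lion
lip
list
listen
little
live
load
long
look
lose
lost
lot
loud
love
low
luck
lunch
machine
made
mail
main
make
man
many
map
march
mark
market
marry
master
match
matter
may
maybe
me
meal
mean
meant
measure
meat
meet
member
men
mend
middle
might
mile
milk
mind
mine
minute
miss
mistake
moment
money
month
moon
more
morning
most
mother
mountain
mouse
mouth
move
much
mud
music
must
my
myself
name
near
neck
need
neighbor
neither
nest
never
new
news
next
nice
night
nine
no
nobody
noise
none
noon
nor
north
nose
not
note
nothing
now
number
nut
ocean
of
off
offer
office
often
oh
old
on
once
one
only
open
or
orange
order
other
ought
our
out
outside
over
own
page
paid
pain
paint
pair
pan
paper
parent
park
part
party
pass
past
pay
peace
pen
pencil
penny
people
perhaps
person
pick
picture
piece
pig
pin
place
plain
plan
plant
play
please
pocket
point
poor
post
pot
pound
pour
power
present
press
pretty
price
print
promise
proud
pull
push
put
queen
question
quick
quiet
quite
rabbit
race
rain
raise
ran
reach
read
ready
real
reason
red
remember
rest
return
rich
ride
right
ring
rise
river
road
rock
roll
roof
room
rope
rose
round
row
rub
rule
run
sad
safe
said
sail
salt
same
sand
sat
save
saw
say
school
sea
season
seat
second
see
seed
seem
seen
self
sell
send
sent
serve
set
seven
several
shake
shall
shape
share
sharp
she
sheep
shine
ship
shirt
shoe
shop
short
should
shoulder
shout
show
shut
sick
side
sight
sign
silver
simple
since
sing
sister
sit
six
size
skin
sky
sleep
slow
small
smell
smile
smoke
snow
so
soap
soft
sold
some
somebody
someone
something
sometimes
son
song
soon
sorry
sort
sound
soup
south
space
speak
special
spell
spend
spent
spoke
spoon
sport
spot
spread
spring
square
stand
star
start
state
stay
step
stick
still
stone
stood
stop
store
storm
story
straight
strange
street
strong
such
sudden
sugar
summer
sun
supper
sure
surprise
sweet
swim
table
tail
take
taken
talk
tall
taste
teach
teacher
team
tear
tell
ten
tent
test
than
thank
that
the
their
them
themselves
then
there
these
they
thick
thin
thing
think
third
thirty
this
those
though
thought
thousand
three
threw
throw
tie
till
time
tiny
tire
tired
to
today
together
told
tomorrow
tonight
too
took
tooth
top
touch
toward
town
toy
train
tree
trick
trip
trouble
true
trust
try
turn
twelve
twenty
two
uncle
under
understand
until
up
upon
us
use
used
useful
very
visit
voice
wait
wake
walk
wall
want
war
warm
was
wash
watch
water
way
we
wear
weather
week
well
went
were
west
wet
what
wheel
when
where
whether
which
while
white
who
whole
whom
whose
why
wide
wife
wild
will
win
wind
window
winter
wise
wish
with
without
woman
women
wonder
wood
word
wore
work
world
would
write
wrong
wrote
yard
year
yellow
yes
yesterday
yet
you
young
your
yourself
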